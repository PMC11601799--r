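#' Wrap an arbitrary discrete map for Lyapunov analysis
#'
#' Bundles a step function and its Jacobian so that
#' [lyapunov_exponent()] can be applied to maps other than the built-in
#' beetle models (useful for closed-form cross-checks, e.g. the linear map
#' `x -> a x` whose exponent is `ln a`).
#'
#' @param step function(state) -> next state.
#' @param jacobian function(state) -> Jacobian matrix (a 1x1 matrix for
#'   scalar maps).
#' @return An object of class `"discrete_map"`.
#' @export
discrete_map <- function(step, jacobian) {
  stopifnot(is.function(step), is.function(jacobian))
  structure(list(step = step, jacobian = jacobian), class = "discrete_map")
}

as_discrete_map <- function(params) {
  if (inherits(params, "discrete_map")) return(params)
  stopifnot(inherits(params, "beetle_params"))
  step_fn <- if (inherits(params, "lpaa_params")) lpaa_step else lpa_step
  discrete_map(step = function(s) step_fn(params, s),
               jacobian = function(s) model_jacobian(params, s))
}

mat_norm <- function(M, norm = c("spectral", "frobenius")) {
  norm <- match.arg(norm)
  if (norm == "spectral") svd(M, nu = 0, nv = 0)$d[1]
  else sqrt(sum(M * M))
}

#' Lyapunov exponent of an orbit by rescaled Jacobian products
#'
#' Estimates the dominant Lyapunov exponent
#' \deqn{\lambda = \lim_{t\to\infty} \frac{1}{t} \ln \| J_t J_{t-1} \cdots J_1 \|}
#' along an orbit. Direct accumulation of the matrix product overflows or
#' underflows, so the product is renormalised each step: with
#' `s_1 = ||J_1||`, `S_1 = J_1 / s_1` and then `s_t = ||J_t S_{t-1}||`,
#' `S_t = J_t S_{t-1} / s_t`, the exponent is the running mean of
#' `ln s_t`. The telescoping identity `s_1 s_2 ... s_t = ||J_t ... J_1||`
#' holds exactly for any matrix norm, so the estimate is norm-independent at
#' every horizon; the spectral norm (largest singular value) is the default
#' because it yields the tightest per-step scalars.
#'
#' A positive estimate is an indicator of chaos, not a proof of it.
#'
#' @param params an [lpaa_params()], [lpa_params()] or [discrete_map()]
#'   object.
#' @param state0 initial state.
#' @param n_transient steps discarded before accumulation begins.
#' @param n_steps steps accumulated (>= 1).
#' @param norm `"spectral"` or `"frobenius"`.
#' @param align_steps tangent warm-up: over the last `align_steps` of the
#'   transient the renormalised product is propagated (its scalars
#'   discarded) so that accumulation starts from the aligned tangent
#'   direction, as in Benettin-style computations. Without it the estimate
#'   carries an `O(1/n_steps)` offset from the non-normality of the
#'   Jacobians. Set to 0 to start from the bare first Jacobian (the raw
#'   telescoping identity then holds from step one).
#' @return An object of class `"lyapunov_result"`: list with `lambda`,
#'   `n_steps`, `log_sum` (the running sum of `ln s_t`), `norm`.
#' @examples
#' lyapunov_exponent(lpaa_medians(), c(10, 10, 10, 10),
#'                   n_transient = 1000, n_steps = 500)
#' @export
lyapunov_exponent <- function(params, state0, n_transient = 50000,
                              n_steps = 2000, norm = c("spectral", "frobenius"),
                              align_steps = min(500L, n_transient)) {
  norm <- match.arg(norm)
  stopifnot(n_steps >= 1, n_transient >= 0, align_steps <= n_transient)
  map <- as_discrete_map(params)
  state <- state0
  S <- NULL
  for (i in seq_len(n_transient)) {
    if (i > n_transient - align_steps) {
      J <- map$jacobian(state)
      if (!is.matrix(J)) J <- matrix(J, 1, 1)
      M <- if (is.null(S)) J else J %*% S
      s <- mat_norm(M, norm)
      if (is.finite(s) && s > 0) S <- M / s
    }
    state <- map$step(state)
  }
  log_sum <- 0
  for (i in seq_len(n_steps)) {
    J <- map$jacobian(state)
    if (!is.matrix(J)) J <- matrix(J, 1, 1)
    M <- if (is.null(S)) J else J %*% S
    s <- mat_norm(M, norm)
    if (!is.finite(s) || s == 0)
      stop("degenerate orbit: accumulated Jacobian product has norm ", s,
           " at step ", i)
    S <- M / s
    log_sum <- log_sum + log(s)
    state <- map$step(state)
  }
  structure(list(lambda = log_sum / n_steps, n_steps = n_steps,
                 log_sum = log_sum, norm = norm),
            class = "lyapunov_result")
}

#' @export
print.lyapunov_result <- function(x, ...) {
  cat(sprintf("Lyapunov exponent: %.6g per step (%d steps, %s norm)\n",
              x$lambda, x$n_steps, x$norm))
  if (x$lambda > 0) cat("lambda > 0: chaos indicator (not sufficient for chaos)\n")
  invisible(x)
}

#' Detect the period of a settled orbit tail
#'
#' Finds the smallest period `p` such that the sequence repeats with lag `p`
#' within tolerance, i.e. `|x[i] - x[i-p]| <= tol * (1 + max|x|)` for all
#' applicable `i`. Period 1 means a fixed point.
#'
#' @param x numeric vector (a post-transient orbit tail).
#' @param tol relative tolerance.
#' @param max_period largest period tried (default `floor(length(x)/2)`).
#' @return Integer period, or `NA_integer_` if no period is detected.
#' @export
orbit_period <- function(x, tol = 1e-6, max_period = NULL) {
  n <- length(x)
  if (is.null(max_period)) max_period <- n %/% 2L
  scale <- 1 + max(abs(x))
  for (p in seq_len(max_period)) {
    if (all(abs(x[(p + 1):n] - x[1:(n - p)]) <= tol * scale))
      return(as.integer(p))
  }
  NA_integer_
}

#' Bifurcation scan with Lyapunov exponents
#'
#' Implements the standard scan: for each value of the bifurcation
#' parameter, iterate the model from a fixed interior initial state for
#' `n_transient` steps to remove transients, retain the next `n_keep`
#' iterates (plotted in bifurcation diagrams), and accumulate the rescaled
#' Lyapunov exponent over `lyap_steps` post-transient steps. Divergent
#' orbits are recorded and the scan continues.
#'
#' @param params base parameter object; one entry is swept.
#' @param param_name name of the swept parameter (e.g. `"b"`, `"c1"`).
#' @param values numeric grid of parameter values (each must yield a valid
#'   parameter set).
#' @param state0 fixed initial state; defaults to 10 beetles per stage.
#' @param n_transient transient steps discarded (50,000 by default;
#'   5,000 is adequate for desk-scale work).
#' @param n_keep retained post-transient iterates per value.
#' @param lyap_steps steps used for the Lyapunov accumulation.
#' @param norm matrix norm for the rescaling.
#' @return An object of class `"bifurcation_scan"`: a long data frame with
#'   columns `param`, `param_value`, `iterate_index`, the stage columns,
#'   `total`, `lambda` and `diverged`.
#' @examples
#' sc <- bifurcation_scan(lpaa_medians(), "b", c(2, 6.4232, 12),
#'                        n_transient = 2000, lyap_steps = 300)
#' unique(sc[, c("param_value", "lambda")])
#' @export
bifurcation_scan <- function(params, param_name, values,
                             state0 = NULL, n_transient = 50000,
                             n_keep = 100, lyap_steps = 1000,
                             norm = "spectral") {
  stopifnot(inherits(params, "beetle_params"), length(values) > 0)
  if (!param_name %in% param_names(params))
    stop("unknown parameter '", param_name, "' for this model")
  snames <- state_names(params)
  if (is.null(state0)) state0 <- rep(10, length(snames))
  rows <- vector("list", length(values))
  for (k in seq_along(values)) {
    p <- params
    p[[param_name]] <- values[k]
    p <- revalidate_params(p)
    res <- tryCatch({
      tr <- project_population(p, state0, n_transient + n_keep)
      kept <- as.matrix(tr[(n_transient + 2):(n_transient + n_keep + 1), snames])
      lam <- lyapunov_exponent(p, as.numeric(tr[n_transient + 1, snames]),
                               n_transient = 0, n_steps = lyap_steps,
                               norm = norm)$lambda
      list(kept = kept, lambda = lam, diverged = FALSE)
    }, error = function(e) list(kept = matrix(NA_real_, n_keep, length(snames),
                                              dimnames = list(NULL, snames)),
                                lambda = NA_real_, diverged = TRUE))
    df <- data.frame(param = param_name, param_value = values[k],
                     iterate_index = seq_len(n_keep))
    df <- cbind(df, as.data.frame(res$kept))
    df$total <- rowSums(res$kept)
    df$lambda <- res$lambda
    df$diverged <- res$diverged
    rows[[k]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("bifurcation_scan", "data.frame"),
            base_params = params, n_transient = n_transient)
}

#' Write a bifurcation scan to CSV
#' @param scan a `"bifurcation_scan"` data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scan_csv <- function(scan, path) {
  utils::write.csv(as.data.frame(scan), path, row.names = FALSE)
  invisible(path)
}

#' @export
plot.bifurcation_scan <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$param_value, x$total, pch = ".", cex = 2,
                 xlab = x$param[1], ylab = "total population", ...)
  lam <- unique(x[, c("param_value", "lambda")])
  graphics::plot(lam$param_value, lam$lambda, type = "l",
                 xlab = x$param[1], ylab = expression(lambda))
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
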