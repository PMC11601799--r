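default_fit_bounds <- function(model) {
  if (model == "lpaa")
    list(b = c(1e-6, 20), mu_p = c(0, 1 - 1e-6), mu_a = c(1e-6, 1 - 1e-6),
         c1 = c(0, 1), c2 = c(0, 1))
  else
    list(b = c(1e-6, 20), mu_a = c(1e-6, 1 - 1e-6),
         c1 = c(0, 1), c2 = c(0, 1), c3 = c(0, 1))
}

make_params <- function(model, theta, mu_l) {
  if (model == "lpaa")
    structure(list(b = theta[["b"]], mu_l = mu_l, mu_p = theta[["mu_p"]],
                   mu_a = theta[["mu_a"]], c1 = theta[["c1"]], c2 = theta[["c2"]]),
              class = c("lpaa_params", "beetle_params"))
  else
    structure(list(b = theta[["b"]], mu_l = mu_l, mu_a = theta[["mu_a"]],
                   c1 = theta[["c1"]], c2 = theta[["c2"]], c3 = theta[["c3"]]),
              class = c("lpa_params", "beetle_params"))
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Fit a beetle model to census data by one-step forecasting
#'
#' Estimates the parameters of the LPAA (or reference LPA) model by
#' minimising the weighted sum of squared one-step-forecast residuals
#' ([weighted_sse()]) over the supplied census series. Larval mortality
#' `mu_l` is estimated directly from the data ([estimate_larval_mortality()])
#' and held fixed; the remaining parameters are optimised inside biological
#' bounds (recruitment `b` in (0, 20], mortalities in [0, 1), cannibalism
#' coefficients nonnegative) by bounded quasi-Newton descent
#' (`L-BFGS-B`) from Latin-hypercube multi-starts. The objective is
#' nonconvex, hence the multi-start; the run is deterministic given `seed`.
#'
#' @param censuses a [census_series()] or a list of them (all series are
#'   weighted equally; per-group fits are obtained by passing one series).
#' @param model `"lpaa"` or `"lpa"`.
#' @param bounds named list of `c(lower, upper)` bounds overriding the
#'   defaults for any free parameter.
#' @param n_starts number of Latin-hypercube starting points.
#' @param seed integer seed controlling the starting points.
#' @param mu_l optional fixed larval mortality; by default estimated from
#'   the data.
#' @param weights optional per-series weights passed to [weighted_sse()].
#' @param control passed to [stats::optim()] (defaults add a tight
#'   convergence factor).
#' @return An object of class `"beetle_fit"` with components `params` (the
#'   fitted parameter object), `coefficients`, `objective`, `forecasts`
#'   (one-step forecast table across series), `pinned` (parameters at a
#'   bound), `mu_l_estimated`, `starts` (objective per start),
#'   `convergence`, `bounds`, `seed`, `censuses`, `call`. Methods:
#'   `print`, `summary`, `coef`, `residuals`, `fitted`, `predict`, `plot`,
#'   `simulate`.
#' @examples
#' cs <- generate_census(lpaa_medians(), noise = "none", seed = 1,
#'                       anchor_adults = TRUE)
#' fit <- lpaa_fit(cs, n_starts = 5, seed = 1)
#' coef(fit)
#' @export
lpaa_fit <- function(censuses, model = c("lpaa", "lpa"), bounds = NULL,
                     n_starts = 50, seed = NULL, mu_l = NULL,
                     weights = NULL, control = list()) {
  model <- match.arg(model)
  censuses <- as_census_list(censuses)
  if (is.null(weights)) weights <- rep(1, length(censuses))
  weights <- rep_len(weights, length(censuses))
  if (is.null(mu_l)) {
    mu_l <- estimate_larval_mortality(censuses)
    mu_l_estimated <- TRUE
  } else mu_l_estimated <- FALSE
  mu_l <- min(max(mu_l, 1e-9), 1 - 1e-9)

  bnds <- default_fit_bounds(model)
  if (!is.null(bounds)) {
    bad <- setdiff(names(bounds), names(bnds))
    if (length(bad)) stop("unknown bound names: ", paste(bad, collapse = ", "))
    bnds[names(bounds)] <- bounds
  }
  for (nm in names(bnds))
    if (diff(bnds[[nm]]) <= 0) stop("bounds for '", nm, "' are not well-ordered")
  free <- names(bnds)
  lower <- vapply(bnds, `[`, 0, 1L)
  upper <- vapply(bnds, `[`, 0, 2L)

  template_class <- if (model == "lpaa") c("lpaa_params", "beetle_params")
                    else c("lpa_params", "beetle_params")
  frames <- lapply(censuses, function(cs)
    forecast_frame(structure(list(), class = template_class), cs))

  objective <- function(theta) {
    names(theta) <- free
    p <- make_params(model, theta, mu_l)
    tot <- 0
    for (i in seq_along(frames)) {
      pr <- forecast_predict(p, frames[[i]])
      fr <- frames[[i]]
      tot <- tot + weights[i] * (sum((fr$obs_L - pr$L)^2) +
                                 sum((fr$obs_P - pr$P)^2) +
                                 sum((fr$obs_A - pr$A)^2))
    }
    tot
  }

  # analytic gradient of the SSE: the forecasts are elementary in the
  # parameters, and finite differences are unusable here (the cannibalism
  # coefficients act through exp(-c * A2) with A2 of order hundreds).
  gradient <- function(theta) {
    names(theta) <- free
    p <- make_params(model, theta, mu_l)
    g <- stats::setNames(numeric(length(free)), free)
    for (i in seq_along(frames)) {
      fr <- frames[[i]]
      pr <- forecast_predict(p, fr)
      w <- weights[i]
      eL <- 2 * w * (pr$L - fr$obs_L)
      eA <- 2 * w * (pr$A - fr$obs_A)
      if (model == "lpaa") {
        rec <- exp(-p$c1 * fr$A2)
        surv <- exp(-p$c2 * fr$A2)
        g[["b"]]    <- g[["b"]]    + sum(eL * fr$A2 * rec)
        g[["c1"]]   <- g[["c1"]]   - sum(eL * p$b * fr$A2^2 * rec)
        g[["mu_p"]] <- g[["mu_p"]] - sum(eA * fr$P)
        g[["mu_a"]] <- g[["mu_a"]] - sum(eA * fr$A2)
        g[["c2"]]   <- g[["c2"]]   - sum(eA * fr$A1 * fr$A2 * surv)
      } else {
        rec <- exp(-p$c1 * fr$L - p$c2 * fr$A)
        surv <- exp(-p$c3 * fr$A)
        g[["b"]]    <- g[["b"]]    + sum(eL * fr$A * rec)
        g[["c1"]]   <- g[["c1"]]   - sum(eL * fr$L * p$b * fr$A * rec)
        g[["c2"]]   <- g[["c2"]]   - sum(eL * fr$A * p$b * fr$A * rec)
        g[["mu_a"]] <- g[["mu_a"]] - sum(eA * fr$A)
        g[["c3"]]   <- g[["c3"]]   - sum(eA * fr$A * fr$P * surv)
      }
    }
    g
  }

  ctrl <- utils::modifyList(list(factr = 1e3, maxit = 500), control)
  starts <- with_seed(seed, {
    u <- lhs::randomLHS(n_starts, length(free))
    sweep(sweep(u, 2, upper - lower, "*"), 2, lower, "+")
  })
  colnames(starts) <- free

  best <- NULL
  start_obj <- rep(NA_real_, n_starts)
  for (s in seq_len(n_starts)) {
    res <- tryCatch(
      stats::optim(starts[s, ], objective, gradient, method = "L-BFGS-B",
                   lower = lower, upper = upper, control = ctrl),
      error = function(e) NULL)
    if (is.null(res)) next
    start_obj[s] <- res$value
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) stop("all optimisation starts failed")
  # polish the best start
  polish <- tryCatch(
    stats::optim(best$par, objective, gradient, method = "L-BFGS-B",
                 lower = lower, upper = upper,
                 control = utils::modifyList(ctrl, list(factr = 10))),
    error = function(e) NULL)
  if (!is.null(polish) && polish$value <= best$value) best <- polish

  theta <- best$par
  names(theta) <- free
  params <- revalidate_params(make_params(model, theta, mu_l))
  fc <- do.call(rbind, lapply(censuses, function(cs) one_step_forecasts(params, cs)))
  pin_tol <- 1e-6 * (upper - lower)
  pinned <- free[theta - lower < pin_tol | upper - theta < pin_tol]
  structure(list(model = model, params = params,
                 coefficients = unlist(unclass(params)),
                 objective = best$value, forecasts = fc,
                 pinned = pinned, mu_l_estimated = mu_l_estimated,
                 starts = start_obj, convergence = best$convergence,
                 bounds = bnds, seed = seed, weights = weights,
                 censuses = censuses, call = match.call()),
            class = "beetle_fit")
}

#' @export
print.beetle_fit <- function(x, ...) {
  cat(sprintf("%s model fitted to %d census series by one-step forecast SSE\n",
              toupper(x$model), length(x$censuses)))
  print(round(x$coefficients, 6))
  cat(sprintf("objective (weighted SSE): %.6g\n", x$objective))
  if (length(x$pinned))
    cat("note: parameter(s) at a bound: ", paste(x$pinned, collapse = ", "),
        " (possible poor parameterisation)\n", sep = "")
  invisible(x)
}

#' @export
coef.beetle_fit <- function(object, ...) object$coefficients

#' @export
residuals.beetle_fit <- function(object, ...) {
  with(object$forecasts, c(res_L, res_P, res_A))
}

#' @export
fitted.beetle_fit <- function(object, ...) {
  object$forecasts[, c("group", "j", "target", "pred_L", "pred_P", "pred_A")]
}

#' @export
predict.beetle_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$forecasts)
  newdata <- as_census_list(newdata)
  do.call(rbind, lapply(newdata, function(cs) one_step_forecasts(object$params, cs)))
}

#' @export
summary.beetle_fit <- function(object, ...) {
  fc <- object$forecasts
  per_stage <- c(L = sum(fc$res_L^2), P = sum(fc$res_P^2), A = sum(fc$res_A^2))
  qq <- qq_residuals(object)
  out <- list(fit = object, per_stage_sse = per_stage,
              qq_correlation = qq$correlation,
              n_forecasts = nrow(fc))
  class(out) <- "summary.beetle_fit"
  out
}

#' @export
print.summary.beetle_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("forecasts: %d; per-stage SSE: L %.4g, P %.4g, A %.4g\n",
              x$n_forecasts, x$per_stage_sse["L"], x$per_stage_sse["P"],
              x$per_stage_sse["A"]))
  cat(sprintf("QQ straightness (residual normal-quantile correlation): %.4f\n",
              x$qq_correlation))
  invisible(x)
}

#' @export
plot.beetle_fit <- function(x, ...) {
  fc <- x$forecasts
  op <- graphics::par(mfrow = c(3, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  for (st in c("L", "P", "A")) {
    obs <- fc[[paste0("obs_", st)]]; pred <- fc[[paste0("pred_", st)]]
    graphics::plot(fc$target, obs, pch = 16, xlab = "census",
                   ylab = paste(st, "count"), ...)
    graphics::points(fc$target, pred, col = 2, pch = 1)
  }
  invisible(x)
}

#' @export
simulate.beetle_fit <- function(object, nsim = 1, seed = NULL, n_census = 10,
                                ...) {
  if (object$model != "lpaa")
    stop("synthetic census generation is defined for the LPAA model")
  with_seed(seed, {
    seeds <- sample.int(.Machine$integer.max, nsim)
    lapply(seq_len(nsim), function(i)
      generate_census(object$params, n_census = n_census, seed = seeds[i],
                      group = paste0("sim", i), ...))
  })
}

#' Percent improvement of the LPAA fit over the LPA fit
#'
#' `100 * (SSE_LPA - SSE_LPAA) / SSE_LPA`: positive values mean the
#' four-stage model fits better.
#'
#' @param objective_lpa,objective_lpaa objective values (weighted SSE) or
#'   `"beetle_fit"` objects.
#' @return Percent improvement (single number, not rounded).
#' @examples
#' compare_models(2.98e4, 2.25e4)  # +24.5%
#' @export
compare_models <- function(objective_lpa, objective_lpaa) {
  if (inherits(objective_lpa, "beetle_fit")) objective_lpa <- objective_lpa$objective
  if (inherits(objective_lpaa, "beetle_fit")) objective_lpaa <- objective_lpaa$objective
  if (!is.finite(objective_lpa) || objective_lpa <= 0)
    stop("LPA objective must be positive")
  100 * (objective_lpa - objective_lpaa) / objective_lpa
}

#' Normal QQ diagnostics of one-step residuals
#'
#' Pairs the sorted residuals with standard normal quantiles and reports
#' their correlation as a straightness statistic; values near 1 indicate
#' approximately normal residuals (goodness of fit of the one-step
#' forecasts).
#'
#' @param x a `"beetle_fit"` or a numeric vector of residuals (>= 5).
#' @return An object of class `"qq_residuals"`: list with `sample` (sorted
#'   residuals), `theoretical` (normal quantiles), `correlation`,
#'   `degenerate` (TRUE when residuals are constant; correlation is then
#'   `NA`).
#' @export
qq_residuals <- function(x) {
  r <- if (inherits(x, "beetle_fit")) residuals(x) else as.numeric(x)
  if (length(r) < 5) stop("need at least 5 residuals")
  s <- sort(r)
  q <- stats::qnorm(stats::ppoints(length(s)))
  degenerate <- diff(range(s)) == 0
  structure(list(sample = s, theoretical = q,
                 correlation = if (degenerate) NA_real_ else stats::cor(s, q),
                 degenerate = degenerate),
            class = "qq_residuals")
}

#' @export
print.qq_residuals <- function(x, ...) {
  if (x$degenerate) cat("QQ diagnostics: degenerate (constant residuals)\n")
  else cat(sprintf("QQ straightness correlation: %.4f (n = %d)\n",
                   x$correlation, length(x$sample)))
  invisible(x)
}

#' @export
plot.qq_residuals <- function(x, ...) {
  graphics::plot(x$theoretical, x$sample, xlab = "normal quantiles",
                 ylab = "ordered residuals", ...)
  if (!x$degenerate)
    graphics::abline(stats::lm(x$sample ~ x$theoretical), col = 2)
  invisible(x)
}
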