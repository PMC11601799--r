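#' Parameters of the four-stage LPAA beetle model
#'
#' Constructs and validates the demographic and cannibalism parameters of the
#' LPAA map, in which the adult population is stratified into newly emerged
#' (`A1`) and reproductively mature (`A2`) cohorts and mature adults
#' cannibalise both eggs and newly emerged adults.
#'
#' One time step spans two weeks. Cannibalism acts through survival factors
#' `exp(-c * A2)` derived from random-encounter (binomial) survival, so `c1`
#' and `c2` are per-mature-adult encounter intensities.
#'
#' @param b larval recruitment in the absence of cannibalism (larvae per
#'   mature adult per step); must be positive.
#' @param mu_l proportion of larvae lost to natural mortality per step,
#'   strictly inside (0, 1).
#' @param mu_p proportion of pupae lost per step, in \[0, 1). Zero is allowed:
#'   fitted values are numerically indistinguishable from zero.
#' @param mu_a proportion of mature adults lost per step, strictly inside
#'   (0, 1).
#' @param c1 cannibalism intensity of mature adults on eggs (per mature
#'   adult), nonnegative.
#' @param c2 cannibalism intensity of mature adults on newly emerged adults
#'   (per mature adult), nonnegative.
#'
#' @return An object of class `c("lpaa_params", "beetle_params")`: a named
#'   list with the six parameters.
#' @seealso [lpa_params()], [lpaa_step()], [steady_states()]
#' @examples
#' p <- lpaa_params(b = 6.4232, mu_l = 0.6053, mu_p = 0, mu_a = 0.0358,
#'                  c1 = 0.0099, c2 = 0.0028)
#' net_reproductive_number(p)
#' @export
lpaa_params <- function(b, mu_l, mu_p, mu_a, c1, c2) {
  vals <- list(b = b, mu_l = mu_l, mu_p = mu_p, mu_a = mu_a, c1 = c1, c2 = c2)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number")
  }
  if (b <= 0) stop("b must be positive")
  if (mu_l <= 0 || mu_l >= 1) stop("mu_l must lie strictly in (0, 1)")
  if (mu_p < 0 || mu_p >= 1) stop("mu_p must lie in [0, 1)")
  if (mu_a <= 0 || mu_a >= 1) stop("mu_a must lie strictly in (0, 1)")
  if (c1 < 0) stop("c1 must be nonnegative")
  if (c2 < 0) stop("c2 must be nonnegative")
  structure(vals, class = c("lpaa_params", "beetle_params"))
}

#' Parameters of the classical three-stage LPA beetle model
#'
#' The reference larvae-pupae-adults map in which larvae and adults
#' cannibalise eggs (`c1`, `c2`) and adults cannibalise pupae (`c3`).
#'
#' @param b larval recruitment (larvae per adult per step), positive.
#' @param mu_l larval mortality proportion, strictly inside (0, 1).
#' @param mu_a adult mortality proportion, strictly inside (0, 1).
#' @param c1 cannibalism intensity of larvae on eggs, nonnegative.
#' @param c2 cannibalism intensity of adults on eggs, nonnegative.
#' @param c3 cannibalism intensity of adults on pupae, nonnegative.
#'
#' @return An object of class `c("lpa_params", "beetle_params")`.
#' @seealso [lpaa_params()], [lpa_step()]
#' @export
lpa_params <- function(b, mu_l, mu_a, c1, c2, c3) {
  vals <- list(b = b, mu_l = mu_l, mu_a = mu_a, c1 = c1, c2 = c2, c3 = c3)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number")
  }
  if (b <= 0) stop("b must be positive")
  if (mu_l <= 0 || mu_l >= 1) stop("mu_l must lie strictly in (0, 1)")
  if (mu_a <= 0 || mu_a >= 1) stop("mu_a must lie strictly in (0, 1)")
  if (c1 < 0 || c2 < 0 || c3 < 0) stop("cannibalism coefficients must be nonnegative")
  structure(vals, class = c("lpa_params", "beetle_params"))
}

#' @export
print.lpaa_params <- function(x, ...) {
  cat("LPAA model parameters (one step = two weeks)\n")
  cat(sprintf("  b    = %g  (larval recruitment per mature adult)\n", x$b))
  cat(sprintf("  mu_l = %g   mu_p = %g   mu_a = %g\n", x$mu_l, x$mu_p, x$mu_a))
  cat(sprintf("  c1   = %g  (adults on eggs)   c2 = %g  (adults on new adults)\n",
              x$c1, x$c2))
  invisible(x)
}

#' @export
print.lpa_params <- function(x, ...) {
  cat("LPA model parameters (one step = two weeks)\n")
  cat(sprintf("  b    = %g   mu_l = %g   mu_a = %g\n", x$b, x$mu_l, x$mu_a))
  cat(sprintf("  c1   = %g  (larvae on eggs)   c2 = %g  (adults on eggs)   c3 = %g  (adults on pupae)\n",
              x$c1, x$c2, x$c3))
  invisible(x)
}

#' Median fitted parameter sets
#'
#' The median best-fit parameter values across the eight experimental groups
#' of the 20-week biweekly census experiment, for each model.
#'
#' @return A parameter object ([lpaa_params()] or [lpa_params()]).
#' @examples
#' lpaa_medians()
#' @export
lpaa_medians <- function() {
  lpaa_params(b = 6.4232, mu_l = 0.6053, mu_p = 2.64e-12, mu_a = 0.0358,
              c1 = 0.0099, c2 = 0.0028)
}

#' @rdname lpaa_medians
#' @export
lpa_medians <- function() {
  lpa_params(b = 20, mu_l = 0.6053, mu_a = 0.0842,
             c1 = 0.0179, c2 = 0.0003, c3 = 1.0760e-13)
}

param_names <- function(params) {
  if (inherits(params, "lpaa_params")) c("b", "mu_l", "mu_p", "mu_a", "c1", "c2")
  else c("b", "mu_l", "mu_a", "c1", "c2", "c3")
}

revalidate_params <- function(params) {
  if (inherits(params, "lpaa_params"))
    do.call(lpaa_params, unclass(params))
  else
    do.call(lpa_params, unclass(params))
}

#' Read or write a flat parameter configuration file
#'
#' Parameters are stored as a flat key-value mapping (YAML or JSON by file
#' extension) with keys exactly `b, mu_l, mu_p, mu_a, c1, c2` for the LPAA
#' model and `b, mu_l, mu_a, c1, c2, c3` for the LPA model; the model is
#' inferred from which keys are present.
#'
#' @param path file path; extension `.yaml`/`.yml` or `.json`.
#' @param params a parameter object to write.
#' @return `read_params()` returns a parameter object; `write_params()`
#'   returns `path` invisibly.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  vals <- lapply(vals, as.numeric)
  if ("c3" %in% names(vals)) {
    do.call(lpa_params, vals[c("b", "mu_l", "mu_a", "c1", "c2", "c3")])
  } else if ("mu_p" %in% names(vals)) {
    do.call(lpaa_params, vals[c("b", "mu_l", "mu_p", "mu_a", "c1", "c2")])
  } else {
    stop("cannot infer model: need either 'mu_p' (LPAA) or 'c3' (LPA) key")
  }
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "beetle_params"))
  vals <- unclass(params)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(vals, path)
  }
  invisible(path)
}
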