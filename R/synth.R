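#' Generate a synthetic census series from the LPAA model
#'
#' Emulates the structure of the 20-week biweekly laboratory experiment:
#' about ten censuses recording larvae, pupae and *total* adults (the
#' newly emerged and mature cohorts are not distinguishable in a census).
#'
#' Two observation processes are available. With `anchor_adults = FALSE`
#' (default) the latent four-stage LPAA orbit is simulated and its
#' observables recorded — the natural emulation of a real culture. With
#' `anchor_adults = TRUE` the adult cohorts are re-derived from the
#' recorded totals at every step exactly as the one-step-forecast fitting
#' pipeline reconstructs them (`A2 = previous total`, `A1 = increment`);
#' this is the data-generating process for which that pipeline is
#' well-specified, so noise-free data regenerate themselves under
#' [one_step_forecasts()] and parameters are exactly recoverable. The two
#' processes coincide when no adult dies within a census interval
#' (`mu_a = 0`, `c2 = 0`) and differ by a few percent at the fitted
#' medians.
#'
#' @param params true [lpaa_params()].
#' @param state0 initial state at the first census.
#' @param n_census number of censuses (>= 3; default 10, biweekly over 20
#'   weeks with a baseline census).
#' @param noise observation noise model: `"lognormal"` (multiplicative,
#'   mean 1, coefficient of variation `cv`), `"poisson"` (integer counts),
#'   or `"none"`. The experiment reports no error model; these are synthetic
#'   assumptions.
#' @param cv coefficient of variation of the lognormal noise.
#' @param anchor_adults use the census-anchored observation process (see
#'   Details).
#' @param egg_loss_every optional interval (in censuses) of media-change
#'   emulation: every `egg_loss_every`-th census the larval compartment is
#'   reduced by `egg_loss_frac` before recording (`NA` disables it).
#' @param egg_loss_frac fraction of larvae lost at each event.
#' @param seed integer seed; the series is deterministic given the seed.
#' @param group group label.
#' @return A [census_series()] with attribute `truth` (list with the
#'   parameters, initial state, noise settings and seed).
#' @examples
#' cs <- generate_census(lpaa_medians(), seed = 42)
#' cs$adults
#' @export
generate_census <- function(params, state0 = c(L = 100, P = 50, A1 = 20, A2 = 40),
                            n_census = 10, noise = c("lognormal", "none", "poisson"),
                            cv = 0.05, anchor_adults = FALSE,
                            egg_loss_every = NA, egg_loss_frac = 1,
                            seed = NULL, group = "G1") {
  stopifnot(inherits(params, "lpaa_params"))
  noise <- match.arg(noise)
  check_state(state0, 4L)
  if (n_census < 3) stop("n_census must be at least 3")
  if (cv < 0) stop("cv must be nonnegative")
  if (!is.na(egg_loss_every) && (egg_loss_every < 1 || egg_loss_frac < 0 ||
                                 egg_loss_frac > 1))
    stop("invalid egg-loss configuration")

  lat <- matrix(NA_real_, n_census, 3,
                dimnames = list(NULL, c("larvae", "pupae", "adults")))
  state <- as.numeric(state0)
  prev_total <- state[4]  # consistent baseline: split at census 1 is exact
  for (j in seq_len(n_census)) {
    if (!is.na(egg_loss_every) && j %% egg_loss_every == 0)
      state[1] <- state[1] * (1 - egg_loss_frac)
    lat[j, ] <- c(state[1], state[2], state[3] + state[4])
    if (anchor_adults && j > 1) {
      state[3] <- max(lat[j, "adults"] - prev_total, 0)
      state[4] <- prev_total
    }
    prev_total <- lat[j, "adults"]
    state <- as.numeric(lpaa_step(params, state))
  }

  obs <- with_seed(seed, {
    switch(noise,
      none = lat,
      lognormal = {
        sdlog <- sqrt(log(1 + cv^2))
        lat * matrix(stats::rlnorm(length(lat), meanlog = -sdlog^2 / 2,
                                   sdlog = sdlog), nrow(lat))
      },
      poisson = matrix(stats::rpois(length(lat), lat), nrow(lat),
                       dimnames = dimnames(lat)))
  })

  cs <- census_series(group, larvae = obs[, 1], pupae = obs[, 2],
                      adults = obs[, 3])
  attr(cs, "truth") <- list(params = unclass(params), state0 = as.numeric(state0),
                            noise = noise, cv = cv,
                            anchor_adults = anchor_adults,
                            egg_loss_every = egg_loss_every,
                            egg_loss_frac = egg_loss_frac, seed = seed)
  cs
}

#' Generate a multi-group synthetic experiment
#'
#' Produces one census series per experimental group (default 8, as in the
#' laboratory design), sharing the true parameters but with independent
#' observation noise, plus a truth record for recovery scoring.
#'
#' @param params true [lpaa_params()] shared by all groups.
#' @param n_groups number of groups.
#' @param seed master seed; per-group seeds are drawn from it.
#' @param ... further arguments passed to [generate_census()].
#' @return A list with `censuses` (named list of [census_series()]) and
#'   `truth` (parameters, seeds, noise settings), suitable for
#'   [write_truth_json()].
#' @export
generate_experiment <- function(params, n_groups = 8, seed = NULL, ...) {
  stopifnot(n_groups >= 1)
  group_seeds <- with_seed(seed, sample.int(.Machine$integer.max, n_groups))
  censuses <- lapply(seq_len(n_groups), function(g)
    generate_census(params, seed = group_seeds[g],
                    group = sprintf("G%d", g), ...))
  names(censuses) <- vapply(censuses, function(cs) cs$group[1], "")
  extra <- list(...)
  list(censuses = censuses,
       truth = list(params = unclass(params), seed = seed,
                    group_seeds = group_seeds, n_groups = n_groups,
                    settings = extra))
}

#' Score parameter recovery against a truth record
#'
#' Per-parameter relative error `|estimate - truth| / |truth|`; parameters
#' whose true value is zero are reported as absolute error with a name
#' suffix `.abs`.
#'
#' @param truth a truth record (from [generate_experiment()] or a
#'   [lpaa_params()]/[lpa_params()] object).
#' @param fit a `"beetle_fit"` or named numeric vector of estimates.
#' @return Named numeric vector of errors.
#' @export
recovery_error <- function(truth, fit) {
  tv <- if (inherits(truth, "beetle_params")) unlist(unclass(truth))
        else unlist(truth$params)
  est <- if (inherits(fit, "beetle_fit")) coef(fit) else fit
  common <- intersect(names(tv), names(est))
  out <- numeric(0)
  for (nm in common) {
    if (tv[[nm]] == 0) {
      out[paste0(nm, ".abs")] <- abs(est[[nm]])
    } else {
      out[nm] <- abs(est[[nm]] - tv[[nm]]) / abs(tv[[nm]])
    }
  }
  out
}
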