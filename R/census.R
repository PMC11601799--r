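#' Construct a census series
#'
#' A census series records biweekly counts of larvae, pupae and total adults
#' for one experimental group. Adult counts are totals: the census cannot
#' distinguish newly emerged from mature adults, so fitting reconstructs the
#' cohorts via [adult_split()].
#'
#' @param group group label (single string).
#' @param larvae,pupae,adults nonnegative counts, equal lengths, at least 3
#'   censuses (a forecast needs a previous census to split adults and a
#'   following census as target).
#' @param week calendar week of each census; defaults to biweekly spacing
#'   `0, 2, 4, ...`.
#' @param census_index census numbering; defaults to `1..J`.
#' @return A data frame of class `"census_series"` with columns `group`,
#'   `census_index`, `week`, `larvae`, `pupae`, `adults`.
#' @export
census_series <- function(group, larvae, pupae, adults, week = NULL,
                          census_index = seq_along(larvae)) {
  J <- length(larvae)
  if (J < 3L) stop("a census series needs at least 3 censuses")
  if (length(pupae) != J || length(adults) != J)
    stop("larvae, pupae and adults must have equal length")
  counts <- c(larvae, pupae, adults)
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be nonnegative and non-missing")
  if (is.null(week)) week <- 2 * (census_index - 1)
  structure(data.frame(group = as.character(group), census_index = census_index,
                       week = week, larvae = larvae, pupae = pupae,
                       adults = adults),
            class = c("census_series", "data.frame"))
}

as_census_list <- function(censuses) {
  if (inherits(censuses, "census_series")) return(list(censuses))
  if (is.list(censuses) && all(vapply(censuses, inherits, TRUE, "census_series")))
    return(censuses)
  stop("expected a census_series or a list of census_series")
}

#' Estimate larval mortality directly from census data
#'
#' Each fortnight the surviving larvae pupate, so under the model
#' `P(j+1) = (1 - mu_l) L(j)` holds exactly and mu_l is estimable without
#' optimisation: `mu_l = 1 - mean(P(j+1) / L(j))` over censuses with
#' `L(j) > 0`, clipped into `[0, 1)`. With several series the ratios are
#' pooled.
#'
#' @param censuses a [census_series()] or list of them.
#' @return Estimated `mu_l` (single number in `[0, 1)`).
#' @export
estimate_larval_mortality <- function(censuses) {
  censuses <- as_census_list(censuses)
  ratios <- unlist(lapply(censuses, function(cs) {
    J <- nrow(cs)
    j <- which(cs$larvae[-J] > 0)
    cs$pupae[j + 1L] / cs$larvae[j]
  }))
  if (length(ratios) == 0)
    stop("insufficient data: no census pair with positive larval count")
  min(max(1 - mean(ratios), 0), 1 - 1e-12)
}

#' Reconstruct adult cohorts from total adult counts
#'
#' Census data report total adults only. Because adults live much longer
#' than one census interval, the adults present at the previous census are
#' taken as the mature cohort and the increment as the newly emerged cohort:
#' `A1(j) = data(j) - data(j-1)`, `A2(j) = data(j-1)`. A negative increment
#' (declining adult counts) is clipped to zero and flagged.
#'
#' @param census a [census_series()].
#' @param j census index, `2 <= j <= J`.
#' @return Named numeric `c(A1, A2)` with attribute `clipped` (logical).
#' @examples
#' cs <- census_series("G", c(10, 12, 9), c(5, 6, 7), c(10, 14, 13))
#' adult_split(cs, 2)  # A1 = 4, A2 = 10
#' @export
adult_split <- function(census, j) {
  stopifnot(inherits(census, "census_series"))
  J <- nrow(census)
  if (j < 2L || j > J) stop("j must satisfy 2 <= j <= ", J)
  a1 <- census$adults[j] - census$adults[j - 1L]
  clipped <- a1 < 0
  structure(c(A1 = max(a1, 0), A2 = census$adults[j - 1L]), clipped = clipped)
}

# Precompute data-built states and forecast targets for one series.
# For LPAA, states exist for j = 2..J-1 (the split needs j-1, the target is
# j+1); for LPA, j = 1..J-1.
forecast_frame <- function(params, census) {
  J <- nrow(census)
  if (inherits(params, "lpaa_params")) {
    j <- 2:(J - 1L)
    a1 <- pmax(census$adults[j] - census$adults[j - 1L], 0)
    list(j = j,
         L = census$larvae[j], P = census$pupae[j],
         A1 = a1, A2 = census$adults[j - 1L],
         obs_L = census$larvae[j + 1L], obs_P = census$pupae[j + 1L],
         obs_A = census$adults[j + 1L],
         clipped = (census$adults[j] - census$adults[j - 1L]) < 0)
  } else {
    j <- 1:(J - 1L)
    list(j = j,
         L = census$larvae[j], P = census$pupae[j], A = census$adults[j],
         obs_L = census$larvae[j + 1L], obs_P = census$pupae[j + 1L],
         obs_A = census$adults[j + 1L])
  }
}

# Vectorised one-step predictions of the observables (L, P, total adults)
# from a forecast_frame; the workhorse of the SSE objective.
forecast_predict <- function(params, fr) {
  if (inherits(params, "lpaa_params")) {
    pred_A1 <- (1 - params$mu_p) * fr$P
    pred_A2 <- fr$A1 * exp(-params$c2 * fr$A2) + (1 - params$mu_a) * fr$A2
    list(L = params$b * fr$A2 * exp(-params$c1 * fr$A2),
         P = (1 - params$mu_l) * fr$L,
         A1 = pred_A1, A2 = pred_A2, A = pred_A1 + pred_A2)
  } else {
    list(L = params$b * fr$A * exp(-params$c1 * fr$L - params$c2 * fr$A),
         P = (1 - params$mu_l) * fr$L,
         A = fr$P * exp(-params$c3 * fr$A) + (1 - params$mu_a) * fr$A)
  }
}

#' One-step forecasts of a census series
#'
#' For each admissible census `j`, builds the model state from the data
#' (juvenile stages read off directly; for the LPAA model the adult cohorts
#' come from [adult_split()]), advances it one step, and compares the
#' predicted observables with the next census. The observable adult
#' prediction for the LPAA model is the cohort sum `A1 + A2`.
#'
#' @param params a parameter object ([lpaa_params()] or [lpa_params()]).
#' @param census a [census_series()].
#' @return A data frame of class `"one_step_forecast"`: columns `j` (state
#'   census), `target` (= j + 1), predicted and observed `L`, `P`, `A`, and
#'   residuals `res_L`, `res_P`, `res_A` (observed minus predicted). LPAA
#'   forecasts also carry `pred_A1`, `pred_A2` and a `clipped` flag for
#'   negative adult increments.
#' @export
one_step_forecasts <- function(params, census) {
  stopifnot(inherits(params, "beetle_params"), inherits(census, "census_series"))
  fr <- forecast_frame(params, census)
  pr <- forecast_predict(params, fr)
  out <- data.frame(group = census$group[1], j = fr$j, target = fr$j + 1L,
                    pred_L = pr$L, pred_P = pr$P, pred_A = pr$A,
                    obs_L = fr$obs_L, obs_P = fr$obs_P, obs_A = fr$obs_A,
                    res_L = fr$obs_L - pr$L, res_P = fr$obs_P - pr$P,
                    res_A = fr$obs_A - pr$A)
  if (inherits(params, "lpaa_params")) {
    out$pred_A1 <- pr$A1
    out$pred_A2 <- pr$A2
    out$clipped <- fr$clipped
  }
  structure(out, class = c("one_step_forecast", "data.frame"))
}

#' Weighted sum of squared one-step residuals
#'
#' The fitting objective: the sum over census series and over the three
#' observable stages of squared residuals between observations and one-step
#' forecasts. All series are weighted equally by default (weight 1 per
#' stage series); a per-series weight vector is available for sensitivity
#' analysis.
#'
#' @param params a parameter object.
#' @param censuses a [census_series()] or list of them.
#' @param weights optional per-series weights (recycled to the number of
#'   series); default all 1.
#' @return The objective value (single nonnegative number).
#' @export
weighted_sse <- function(params, censuses, weights = NULL) {
  censuses <- as_census_list(censuses)
  if (is.null(weights)) weights <- rep(1, length(censuses))
  weights <- rep_len(weights, length(censuses))
  tot <- 0
  for (i in seq_along(censuses)) {
    fr <- forecast_frame(params, censuses[[i]])
    pr <- forecast_predict(params, fr)
    tot <- tot + weights[i] * (sum((fr$obs_L - pr$L)^2) +
                               sum((fr$obs_P - pr$P)^2) +
                               sum((fr$obs_A - pr$A)^2))
  }
  tot
}
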