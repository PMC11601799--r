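#' Read census series from CSV
#'
#' Expects columns `group, census_index, larvae, pupae, adults` (a `week`
#' column is optional and defaults to biweekly spacing). Rows are validated:
#' negative or missing counts and duplicated `(group, census_index)` pairs
#' are reported with their line numbers (header = line 1).
#'
#' @param path CSV file path.
#' @return A named list of [census_series()], one per group, ordered by
#'   census index.
#' @export
read_census_csv <- function(path) {
  if (!file.exists(path)) stop("census file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("group", "census_index", "larvae", "pupae", "adults")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  counts <- as.matrix(df[, c("larvae", "pupae", "adults")])
  bad <- which(rowSums(is.na(counts) | counts < 0) > 0)
  if (length(bad))
    stop("negative or missing counts at line(s) ",
         paste(bad + 1L, collapse = ", "))
  dup <- which(duplicated(df[, c("group", "census_index")]))
  if (length(dup))
    stop("duplicate (group, census_index) at line(s) ",
         paste(dup + 1L, collapse = ", "))
  if (!"week" %in% names(df)) df$week <- 2 * (df$census_index - 1)
  out <- lapply(split(df, df$group), function(g) {
    g <- g[order(g$census_index), ]
    census_series(g$group[1], g$larvae, g$pupae, g$adults,
                  week = g$week, census_index = g$census_index)
  })
  out[order(names(out))]
}

#' Write census series to CSV
#'
#' Inverse of [read_census_csv()]: columns `group, census_index, week,
#' larvae, pupae, adults`.
#'
#' @param censuses a [census_series()] or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_census_csv <- function(censuses, path) {
  censuses <- as_census_list(censuses)
  df <- do.call(rbind, lapply(censuses, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialise a truth record or fit result to JSON
#'
#' `write_truth_json()` stores the generating parameters, seeds and noise
#' settings of a synthetic experiment; `write_fit_json()` stores the
#' estimated parameters, objective, residuals and metadata of a
#' `"beetle_fit"`. Both embed the seed used, so runs can be replayed.
#'
#' @param truth the `truth` component of [generate_experiment()] (or the
#'   `truth` attribute of a single [generate_census()] series).
#' @param fit a `"beetle_fit"` object.
#' @param path output file path.
#' @return `path` invisibly; `read_truth_json()` returns the truth list
#'   with the parameter object restored.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  truth <- jsonlite::read_json(path, simplifyVector = TRUE)
  pars <- lapply(truth$params, as.numeric)
  truth$params <- if ("c3" %in% names(pars)) do.call(lpa_params, pars)
                  else do.call(lpaa_params, pars)
  truth
}

#' @rdname write_truth_json
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "beetle_fit"))
  out <- list(model = fit$model,
              parameters = as.list(fit$coefficients),
              objective = fit$objective,
              pinned = fit$pinned,
              mu_l_estimated = fit$mu_l_estimated,
              seed = fit$seed,
              convergence = fit$convergence,
              residuals = list(L = fit$forecasts$res_L,
                               P = fit$forecasts$res_P,
                               A = fit$forecasts$res_A))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Write one-step forecasts to CSV
#' @param fit a `"beetle_fit"` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_forecast_csv <- function(fit, path) {
  stopifnot(inherits(fit, "beetle_fit"))
  utils::write.csv(as.data.frame(fit$forecasts), path, row.names = FALSE)
  invisible(path)
}
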