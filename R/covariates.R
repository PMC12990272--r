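# Per-subject reduction of longitudinal laboratory variables.
#
# Each (subject, variable) series is reduced to three scalars: the
# monitoring-period arithmetic mean, the baseline at treatment initiation,
# and the average rate of change obtained from a penalized cubic regression
# spline smoother (REML smoothness selection) evaluated on a 200-point grid
# and differenced between consecutive grid points. The mean of the forward
# differences telescopes to (last - first prediction) / time range, an
# identity asserted internally.

#' Mean and baseline of one covariate series
#'
#' Baseline is the latest measurement at or before treatment initiation
#' (day <= `init_day`); when none exists, the first available measurement.
#'
#' @param series data.frame with columns `day`, `value` for one
#'   (subject, variable) pair.
#' @param init_day treatment-initiation day (default 1; day 0 samples are
#'   pre-initiation labs).
#' @return list: `mean_value`, `baseline_value`, `n_obs`.
#' @export
summarize_covariate <- function(series, init_day = 1L) {
  series <- as.data.frame(series)
  series <- series[is.finite(series$value), , drop = FALSE]
  if (!nrow(series))
    tpk_stop("covariate_empty", "no measurements in covariate series")
  series <- series[order(series$day), , drop = FALSE]
  pre <- series[series$day <= init_day, , drop = FALSE]
  baseline <- if (nrow(pre)) pre$value[nrow(pre)] else series$value[1]
  list(mean_value = mean(series$value), baseline_value = baseline,
       n_obs = nrow(series))
}

#' Smooth-trajectory mean derivative of one covariate series
#'
#' Fits a penalized cubic regression spline (basis dimension
#' `min(10, n_obs - 1)`, REML smoothness selection) to (day, value),
#' predicts on 200 evenly spaced points spanning the observed day range,
#' and returns the mean of the 199 consecutive forward differences divided
#' by the grid step — the average rate of change in units/day. Series with
#' fewer than 4 points fall back to the OLS line slope, flagged in the
#' result.
#'
#' @param series data.frame with columns `day`, `value`.
#' @param grid_size number of prediction grid points (default 200).
#' @return list: `slope` (units/day), `method` (`"spline"` or `"ols"`),
#'   `grid` (data.frame day, fitted) for the spline branch.
#' @export
trajectory_slope <- function(series, grid_size = 200L) {
  series <- as.data.frame(series)
  series <- series[is.finite(series$value), , drop = FALSE]
  series <- unique(series[order(series$day), c("day", "value")])
  if (length(unique(series$day)) < 2)
    tpk_stop("trajectory_too_few_days",
             "need measurements on >= 2 distinct days")
  rng <- range(series$day)
  if (nrow(series) < 4) {
    fit <- stats::lm(value ~ day, data = series)
    return(list(slope = unname(stats::coef(fit)[2]), method = "ols",
                grid = NULL))
  }
  if (stats::var(series$value) == 0) {
    grid_day <- seq(rng[1], rng[2], length.out = grid_size)
    return(list(slope = 0, method = "constant",
                grid = data.frame(day = grid_day,
                                  fitted = rep(series$value[1], grid_size))))
  }
  kdim <- max(3L, min(10L, nrow(series) - 1L))
  gm <- mgcv::gam(value ~ s(day, bs = "cr", k = kdim), data = series,
                  method = "REML")
  grid_day <- seq(rng[1], rng[2], length.out = grid_size)
  fitted <- as.numeric(mgcv::predict.gam(gm, data.frame(day = grid_day)))
  step <- diff(grid_day)[1]
  slopes <- diff(fitted) / step
  slope <- mean(slopes)
  # forward differences over a uniform grid telescope exactly
  telescoped <- (fitted[grid_size] - fitted[1]) / (rng[2] - rng[1])
  stopifnot(abs(slope - telescoped) <= 1e-8 * max(1, abs(telescoped)))
  list(slope = slope, method = "spline",
       grid = data.frame(day = grid_day, fitted = fitted))
}

#' Covariate summaries for a whole cohort
#'
#' Long per-subject summary table of every laboratory variable: the
#' monitoring-period mean, the baseline value (suffix `_baseline`) and the
#' smooth-trajectory mean derivative (suffix `_trajectory`).
#'
#' @param dataset a [cohort_dataset].
#' @param init_day treatment-initiation day passed to
#'   [summarize_covariate].
#' @return data.frame: subject_id, variable, kind
#'   (`mean` / `baseline` / `trajectory`), value. The `variable` column for
#'   baseline and trajectory rows carries the suffix convention
#'   (`ALT_baseline`, `ALT_trajectory`).
#' @export
cohort_covariate_summaries <- function(dataset, init_day = 1L) {
  cv <- dataset$covariates
  if (!nrow(cv))
    return(data.frame(subject_id = character(), variable = character(),
                      kind = character(), value = numeric()))
  keys <- unique(cv[c("subject_id", "variable")])
  rows <- lapply(seq_len(nrow(keys)), function(r) {
    s <- cv[cv$subject_id == keys$subject_id[r] &
            cv$variable == keys$variable[r], c("day", "value")]
    base <- summarize_covariate(s, init_day)
    out <- data.frame(
      subject_id = keys$subject_id[r],
      variable = c(keys$variable[r],
                   paste0(keys$variable[r], "_baseline")),
      kind = c("mean", "baseline"),
      value = c(base$mean_value, base$baseline_value))
    if (length(unique(s$day[is.finite(s$value)])) >= 2) {
      ts <- trajectory_slope(s)
      out <- rbind(out, data.frame(
        subject_id = keys$subject_id[r],
        variable = paste0(keys$variable[r], "_trajectory"),
        kind = "trajectory", value = ts$slope))
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
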