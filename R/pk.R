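# Trough-derived surrogate PK endpoints.
#
# With only pre-dose (trough) samples available, classical single-dose
# absorption metrics are undefined; instead the pipeline characterizes
# accumulation over the monitoring window with five surrogates per subject:
# C0,max (highest observed trough), t(C0,max) (the day it occurs), the
# linear-trapezoid AUC of the trough-versus-day curve, the average
# accumulation ratio (mean of each trough over the first measurable trough),
# and AUC per total administered dose.

#' Tukey-fence outlier removal
#'
#' Removes values outside `[lower hinge - 1.5 IQR, upper hinge + 1.5 IQR]`,
#' with hinges from the five-number summary (Tukey hinge) convention — the
#' same fences `grDevices::boxplot.stats()` draws.
#'
#' @param values numeric vector (NAs are kept in place and never flagged).
#' @return list with `kept` (values inside the fences, original order),
#'   `removed_idx` (integer positions flagged as outliers), and `fences`.
#' @export
remove_outliers <- function(values) {
  finite <- is.finite(values)
  if (!any(finite))
    tpk_stop("outlier_no_data", "need at least one finite value")
  st <- grDevices::boxplot.stats(values[finite], do.conf = FALSE)
  hinges <- st$stats[c(2, 4)]  # Tukey hinges from the five-number summary
  iqr <- hinges[2] - hinges[1]
  fences <- c(lower = hinges[1] - 1.5 * iqr, upper = hinges[2] + 1.5 * iqr)
  out <- finite & (values < fences["lower"] | values > fences["upper"])
  if (all(out[finite]))
    tpk_stop("outlier_degenerate", "all values flagged as outliers")
  list(kept = values[!out], removed_idx = which(out), fences = fences)
}

#' Linear trapezoidal AUC of a trough series
#'
#' Cumulative exposure over the monitoring window: the sum over consecutive
#' observation pairs of `(C_j + C_{j+1}) / 2 * (day_{j+1} - day_j)`. This is
#' a partial cumulative-exposure index over irregular trough sampling, not a
#' dosing-interval AUC.
#'
#' @param series data.frame with columns `day`, `concentration` (any row
#'   order; sorted by day internally).
#' @return AUC in ng*day/mL.
#' @export
compute_auc <- function(series) {
  series <- sort_series(series)
  n <- nrow(series)
  if (n < 2)
    tpk_stop("auc_too_few", "AUC requires at least 2 observations (got %d)", n)
  d <- series$day
  cc <- series$concentration
  sum((cc[-n] + cc[-1]) / 2 * diff(d))
}

#' Maximum trough and its day
#'
#' The highest observed trough concentration and the (1-based) day on which
#' it occurs; ties are broken by the earliest day.
#'
#' @param series data.frame with columns `day`, `concentration`.
#' @return list `(c0_max, t_c0_max)`.
#' @export
compute_peak <- function(series) {
  series <- sort_series(series)
  if (!nrow(series))
    tpk_stop("peak_empty", "empty trough series")
  i <- which.max(series$concentration)  # first maximum = earliest day
  list(c0_max = series$concentration[i], t_c0_max = series$day[i])
}

#' Accumulation index and average accumulation ratio
#'
#' Ratio of the trough at each time point to the first measurable trough of
#' the same subject (the first ratio is exactly 1); the mean of the ratios
#' is the average accumulation ratio.
#'
#' @param series data.frame with columns `day`, `concentration`.
#' @return list with `index` (data.frame day, ratio) and `mean_ratio`.
#' @export
accumulation_index <- function(series) {
  series <- sort_series(series)
  if (!nrow(series))
    tpk_stop("index_empty", "empty trough series")
  ref <- series$concentration[1]
  if (!is.finite(ref) || ref <= 0)
    tpk_stop("index_bad_reference",
             "first measurable trough must be positive (got %g)", ref)
  ratio <- series$concentration / ref
  list(index = data.frame(day = series$day, ratio = ratio),
       mean_ratio = mean(ratio))
}

sort_series <- function(series) {
  series <- as.data.frame(series)
  if (anyDuplicated(series$day))
    tpk_stop("series_duplicate_day", "duplicate days in trough series")
  series[order(series$day), , drop = FALSE]
}

#' Per-subject surrogate PK endpoints
#'
#' Assembles all five endpoints for one subject from a trough series and the
#' subject's dose history.
#'
#' @param series data.frame (day, concentration) for one subject.
#' @param dose_total total administered dose over the window, mg (> 0).
#' @param subject_id optional id carried into the result.
#' @return list of class `pk_surrogates`: c0_max, t_c0_max, auc_c0_time,
#'   avg_accumulation_ratio, auc_per_dose, accumulation_index.
#' @export
compute_pk_surrogates <- function(series, dose_total, subject_id = NA_character_) {
  if (!is.finite(dose_total) || dose_total <= 0)
    tpk_stop("dose_nonpositive",
             "subject %s: total dose must be > 0 for dose-normalized endpoints",
             subject_id)
  peak <- compute_peak(series)
  acc <- accumulation_index(series)
  auc <- compute_auc(series)
  structure(list(
    subject_id = subject_id,
    c0_max = peak$c0_max, t_c0_max = peak$t_c0_max,
    auc_c0_time = auc,
    avg_accumulation_ratio = acc$mean_ratio,
    auc_per_dose = auc / dose_total,
    accumulation_index = acc$index), class = "pk_surrogates")
}

#' Surrogate PK endpoints for every subject of a cohort
#'
#' @param dataset a [cohort_dataset].
#' @param use_imputed if `FALSE`, imputed rows (flagged by [impute_daily])
#'   are dropped before computing endpoints.
#' @return data.frame, one row per subject with >= 2 observations:
#'   subject_id, c0_max, t_c0_max, auc_c0_time, avg_accumulation_ratio,
#'   auc_per_dose.
#' @export
cohort_pk_surrogates <- function(dataset, use_imputed = TRUE) {
  td <- total_dose(dataset)
  subjects <- cohort_subjects(dataset)
  rows <- lapply(subjects, function(id) {
    s <- trough_series(dataset, id)
    if (!use_imputed) s <- s[!s$imputed, , drop = FALSE]
    if (nrow(s) < 2) return(NULL)
    pk <- compute_pk_surrogates(s, td[[id]], id)
    data.frame(subject_id = id, c0_max = pk$c0_max, t_c0_max = pk$t_c0_max,
               auc_c0_time = pk$auc_c0_time,
               avg_accumulation_ratio = pk$avg_accumulation_ratio,
               auc_per_dose = pk$auc_per_dose)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(subject_id = character(), c0_max = numeric(),
                      t_c0_max = integer(), auc_c0_time = numeric(),
                      avg_accumulation_ratio = numeric(),
                      auc_per_dose = numeric())
  rownames(out) <- NULL
  out
}

#' @export
print.pk_surrogates <- function(x, ...) {
  cat(sprintf("<pk_surrogates> subject %s\n", x$subject_id))
  cat(sprintf("  C0,max      %.3f ng/mL on day %d\n", x$c0_max, x$t_c0_max))
  cat(sprintf("  AUC(C0,t)   %.3f ng*day/mL (%.5f per mg)\n",
              x$auc_c0_time, x$auc_per_dose))
  cat(sprintf("  avg accumulation ratio %.3f over %d points\n",
              x$avg_accumulation_ratio, nrow(x$accumulation_index)))
  invisible(x)
}
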