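# Mixed-model gap filling for longitudinal trough profiles.
#
# Routine TDM sampling leaves intermittent gaps (alternate-day and 3-4-day
# spacing, plus missed draws). To obtain one concentration per day the
# pipeline fits a linear mixed model on the log scale,
#   log C_ij = (b0 + b0_i) + (b1 + b1_i) * day_ij + e_ij,
# with independent subject-level random intercept and slope (diagonal
# covariance), estimated by REML, and fills missing days with
# exp(subject-specific BLUP prediction). Observed values are never altered.

#' Fit the log-trough linear mixed model
#'
#' @param dataset a [cohort_dataset]; imputed rows are excluded from fitting.
#' @param random_effects `"intercept_slope"` (default; independent random
#'   intercept and day slope) or `"intercept"` (random intercept only).
#' @return object of class `trough_lmm`: fixed effects (`beta0`, `beta1` on
#'   the log ng/mL scale), variance components (`sigma2_b0`, `sigma2_b1`,
#'   `sigma2_e`), per-subject BLUPs, REML log-likelihood, convergence flag,
#'   and the underlying `lmerMod` fit. If the cohort lies exactly on one
#'   shared line (zero residual variance, a boundary where the REML
#'   criterion is undefined) a degenerate fit with the OLS line and zero
#'   variance components is returned with `degenerate = TRUE`.
#' @export
fit_lmm_log_troughs <- function(dataset,
                                random_effects = c("intercept_slope",
                                                   "intercept")) {
  random_effects <- match.arg(random_effects)
  tr <- dataset$troughs[!dataset$troughs$imputed, , drop = FALSE]
  subjects <- unique(tr$subject_id)
  if (length(subjects) < 2)
    tpk_stop("lmm_too_few_subjects", "need >= 2 subjects (got %d)",
             length(subjects))
  obs_per <- table(tr$subject_id)
  if (max(obs_per) < 2)
    tpk_stop("lmm_too_few_obs", "at least one subject needs >= 2 observations")
  df <- data.frame(subject = factor(tr$subject_id), day = tr$day,
                   y = log(tr$concentration))

  # Exactly-shared-line cohorts put the REML optimum on the sigma_e -> 0
  # boundary; short-circuit with the OLS line.
  ols <- stats::lm(y ~ day, data = df)
  if (mean(stats::residuals(ols)^2) < 1e-16) {
    blups <- data.frame(subject_id = as.character(subjects), b0 = 0, b1 = 0)
    return(structure(list(
      beta0 = unname(stats::coef(ols)[1]), beta1 = unname(stats::coef(ols)[2]),
      sigma2_b0 = 0, sigma2_b1 = 0, sigma2_e = 0,
      blups = blups, reml_loglik = NA_real_, converged = TRUE,
      degenerate = TRUE, random_effects = random_effects, model = NULL),
      class = "trough_lmm"))
  }

  form <- if (random_effects == "intercept_slope")
    y ~ day + (1 + day || subject) else y ~ day + (1 | subject)
  fit <- suppressWarnings(lme4::lmer(
    form, data = df, REML = TRUE,
    control = lme4::lmerControl(
      optimizer = "bobyqa",
      check.conv.singular = "ignore",
      check.nobs.vs.nlev = "ignore",
      check.nobs.vs.nRE = "ignore")))
  # hard failure only when the optimizer itself reports one; small-sample
  # gradient-check messages are retained but not fatal
  if (!is.null(fit@optinfo$conv$opt) && fit@optinfo$conv$opt != 0)
    tpk_stop("lmm_nonconvergence",
             "mixed model did not converge (REML criterion %.6f)",
             as.numeric(lme4::REMLcrit(fit)))

  vc <- as.data.frame(lme4::VarCorr(fit))
  getvc <- function(var) {
    v <- vc$vcov[!is.na(vc$var1) & vc$var1 == var]
    if (length(v)) v[1] else 0
  }
  re <- lme4::ranef(fit)$subject
  blups <- data.frame(
    subject_id = rownames(re),
    b0 = re[["(Intercept)"]],
    b1 = if ("day" %in% names(re)) re[["day"]] else 0)
  fe <- lme4::fixef(fit)
  structure(list(
    beta0 = unname(fe[["(Intercept)"]]), beta1 = unname(fe[["day"]]),
    sigma2_b0 = getvc("(Intercept)"), sigma2_b1 = getvc("day"),
    sigma2_e = stats::sigma(fit)^2,
    blups = blups,
    reml_loglik = as.numeric(stats::logLik(fit)),
    converged = TRUE, degenerate = FALSE,
    random_effects = random_effects, model = fit),
    class = "trough_lmm")
}

#' @export
print.trough_lmm <- function(x, ...) {
  cat("<trough_lmm> log C ~ day, REML",
      if (x$degenerate) "(degenerate noiseless fit)", "\n")
  cat(sprintf("  fixed:    intercept %.4f, slope %.5f /day\n",
              x$beta0, x$beta1))
  cat(sprintf("  variance: b0 %.4g, b1 %.4g, residual %.4g\n",
              x$sigma2_b0, x$sigma2_b1, x$sigma2_e))
  cat(sprintf("  subjects: %d; REML logLik %.3f\n",
              nrow(x$blups), x$reml_loglik))
  invisible(x)
}

#' @export
coef.trough_lmm <- function(object, ...) {
  c(intercept = object$beta0, day = object$beta1)
}

#' Subject-specific predictions from a trough mixed model
#'
#' @param object a `trough_lmm`.
#' @param newdata data.frame with columns `subject_id`, `day`.
#' @param type `"response"` (ng/mL, back-transformed without bias
#'   correction) or `"log"`.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.trough_lmm <- function(object, newdata,
                               type = c("response", "log"), ...) {
  type <- match.arg(type)
  idx <- match(newdata$subject_id, object$blups$subject_id)
  if (anyNA(idx))
    tpk_stop("lmm_unknown_subject", "subject(s) absent from fit: %s",
             paste(unique(newdata$subject_id[is.na(idx)]), collapse = ", "))
  lp <- (object$beta0 + object$blups$b0[idx]) +
        (object$beta1 + object$blups$b1[idx]) * newdata$day
  if (type == "log") lp else exp(lp)
}

#' Fill trough gaps to one concentration per day
#'
#' For each subject, every integer day from the first to the last observed
#' day carries a concentration: observed values are preserved unchanged, and
#' missing days receive the exponentiated subject-specific prediction from
#' the mixed model, flagged in the `imputed` column. No extrapolation beyond
#' the observed range.
#'
#' @param dataset a [cohort_dataset].
#' @param fit a converged [fit_lmm_log_troughs] fit on this cohort.
#' @return a new `cohort_dataset` with daily trough coverage.
#' @export
impute_daily <- function(dataset, fit) {
  stopifnot(inherits(fit, "trough_lmm"))
  tr <- dataset$troughs
  filled <- lapply(unique(tr$subject_id), function(id) {
    s <- tr[tr$subject_id == id, , drop = FALSE]
    gaps <- setdiff(seq(min(s$day), max(s$day)), s$day)
    if (!length(gaps)) return(s)
    pred <- predict(fit, data.frame(subject_id = id, day = gaps),
                    type = "response")
    rbind(s, data.frame(subject_id = id, day = as.integer(gaps),
                        concentration = pred, imputed = TRUE))
  })
  troughs <- do.call(rbind, filled)
  cohort_dataset(troughs, dataset$doses, dataset$covariates,
                 dataset$genotypes, dataset$antibiotics,
                 lloq = dataset$lloq,
                 provenance = paste0(dataset$provenance, " + impute_daily"))
}

# Exact two-sided signed-rank p by enumeration of all 2^n sign patterns.
# Unlike the exact path of wilcox.test, this remains exact when absolute
# differences are tied (ties get average ranks). Zero differences are
# dropped first, per the signed-rank convention.
exact_signed_rank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vdist <- as.numeric(signs %*% r)
  p <- min(1, 2 * min(mean(vdist <= v), mean(vdist >= v)))
  list(statistic = v, p_value = p)
}

#' Paired comparison of PK endpoints before and after imputation
#'
#' Two-sided paired Wilcoxon signed-rank test per endpoint over subjects.
#' For 12 or fewer non-zero differences the p-value is computed by exact
#' enumeration of all sign patterns (valid under tied absolute
#' differences); larger samples use `stats::wilcox.test`. Endpoints whose
#' paired differences are all zero are reported as `"identical"` with no
#' p-value rather than a fabricated statistic.
#'
#' @param pk_before,pk_after data.frames from [cohort_pk_surrogates] on the
#'   original and imputed cohorts (same subject set).
#' @return data.frame: metric, n, statistic (V), p_value, note.
#' @export
compare_original_imputed <- function(pk_before, pk_after) {
  metrics <- c("c0_max", "t_c0_max", "auc_c0_time",
               "avg_accumulation_ratio", "auc_per_dose")
  if (!setequal(pk_before$subject_id, pk_after$subject_id))
    tpk_stop("compare_subject_mismatch",
             "before/after endpoint tables cover different subjects")
  m <- match(pk_before$subject_id, pk_after$subject_id)
  rows <- lapply(metrics, function(mt) {
    x <- pk_before[[mt]]
    y <- pk_after[[mt]][m]
    if (all(x == y)) {
      return(data.frame(metric = mt, n = length(x), statistic = NA_real_,
                        p_value = NA_real_, note = "identical"))
    }
    d <- x - y
    if (sum(d != 0) <= 12) {
      ex <- exact_signed_rank(d)
      data.frame(metric = mt, n = length(x), statistic = ex$statistic,
                 p_value = ex$p_value, note = "exact")
    } else {
      wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                                alternative = "two.sided"))
      data.frame(metric = mt, n = length(x),
                 statistic = unname(wt$statistic), p_value = wt$p.value,
                 note = "")
    }
  })
  do.call(rbind, rows)
}
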