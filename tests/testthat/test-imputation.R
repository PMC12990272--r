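shared_line_cohort <- function(subjects = 5, days = 1:10) {
  make_cohort(function(i, d) exp(1.0 + 0.05 * d),
              subjects = sprintf("S%d", seq_len(subjects)), days = days)
}

test_that("a noiseless shared line is recovered with zero variance", {
  fit <- fit_lmm_log_troughs(shared_line_cohort())
  expect_equal(fit$beta0, 1.0, tolerance = 1e-8)
  expect_equal(fit$beta1, 0.05, tolerance = 1e-8)
  expect_lte(fit$sigma2_b0, 1e-6)
  expect_lte(fit$sigma2_b1, 1e-6)
  expect_lte(fit$sigma2_e, 1e-6)
  expect_true(fit$converged)
})

test_that("balanced random-intercept REML matches the closed-form estimator", {
  set.seed(99)
  m <- 100; nd <- 10; days <- 1:nd
  b <- rnorm(m, 0, 0.5)
  tr <- do.call(rbind, lapply(1:m, function(i)
    data.frame(subject_id = sprintf("S%03d", i), day = days,
               concentration = exp(1 + 0.05 * days + b[i] +
                                   rnorm(nd, 0, 0.2)))))
  doses <- data.frame(subject_id = unique(tr$subject_id), day = 1, dose = 3)
  ds <- cohort_dataset(tr, doses, lloq = 0)
  fit <- fit_lmm_log_troughs(ds, random_effects = "intercept")

  # closed-form balanced one-way random-effects REML (ANOVA estimator):
  # residual MS of the fixed-effects fit with subject indicators, and the
  # between-subject mean square corrected for the within-subject part.
  y <- log(tr$concentration)
  subj <- factor(tr$subject_id)
  s2e <- sum(residuals(lm(y ~ tr$day + subj))^2) / (m * nd - m - 1)
  ybar <- tapply(y, subj, mean)
  s2b <- sum((ybar - mean(ybar))^2) / (m - 1) - s2e / nd
  expect_equal(fit$sigma2_e, s2e, tolerance = 1e-6)
  expect_equal(fit$sigma2_b0, s2b, tolerance = 1e-6)
  expect_true(is.finite(fit$reml_loglik))
})

test_that("REML optimum beats random restarts of the deviance function", {
  set.seed(5)
  m <- 15; days <- 1:12
  tr <- do.call(rbind, lapply(1:m, function(i)
    data.frame(subject_id = sprintf("S%02d", i), day = days,
               concentration = exp(0.8 + 0.04 * days + rnorm(1, 0, 0.4) +
                                   rnorm(1, 0, 0.02) * days +
                                   rnorm(length(days), 0, 0.15)))))
  doses <- data.frame(subject_id = unique(tr$subject_id), day = 1, dose = 3)
  ds <- cohort_dataset(tr, doses, lloq = 0)
  fit <- fit_lmm_log_troughs(ds)
  df <- data.frame(subject = factor(tr$subject_id), day = tr$day,
                   y = log(tr$concentration))
  devfun <- lme4::lmer(y ~ day + (1 + day || subject), data = df, REML = TRUE,
                       devFunOnly = TRUE)
  opt <- devfun(lme4::getME(fit$model, "theta"))
  for (r in 1:50) {
    theta <- runif(2, 0, 3)
    expect_gte(devfun(theta) + 1e-8, opt)
  }
})

test_that("imputation fills gaps on the fitted line and preserves data", {
  ds <- shared_line_cohort()
  # knock out interior days for one subject
  tr <- ds$troughs
  tr <- tr[!(tr$subject_id == "S1" & tr$day %in% c(3, 5, 6)), ]
  gappy <- cohort_dataset(tr[c("subject_id", "day", "concentration")],
                          ds$doses)
  fit <- fit_lmm_log_troughs(gappy)
  filled <- impute_daily(gappy, fit)

  s1 <- trough_series(filled, "S1")
  expect_equal(s1$day, 1:10)
  expect_equal(s1$imputed, s1$day %in% c(3, 5, 6))
  expect_equal(s1$concentration[s1$imputed],
               exp(1.0 + 0.05 * c(3, 5, 6)), tolerance = 1e-8)
  # observed values byte-identical, untouched subjects byte-identical
  expect_equal(s1[!s1$imputed, ], trough_series(gappy, "S1"),
               ignore_attr = TRUE)
  expect_identical(trough_series(filled, "S2"), trough_series(gappy, "S2"))

  # gap-free cohort: imputation is the identity
  same <- impute_daily(ds, fit_lmm_log_troughs(ds))
  expect_equal(same$troughs, ds$troughs, ignore_attr = TRUE)
})

test_that("prediction refuses subjects absent from the fit", {
  fit <- fit_lmm_log_troughs(shared_line_cohort())
  err <- tryCatch(predict(fit, data.frame(subject_id = "ghost", day = 2)),
                  troughpk_error = identity)
  expect_equal(err$code, "lmm_unknown_subject")
})

test_that("full-model REML recovery is accurate at moderate size", {
  set.seed(71)
  m <- 150; days <- sort(sample(1:28, 14))
  b0 <- rnorm(m, 0, sqrt(0.16)); b1 <- rnorm(m, 0, sqrt(0.004))
  tr <- do.call(rbind, lapply(1:m, function(i)
    data.frame(subject_id = sprintf("S%03d", i), day = days,
               concentration = exp(0.9 + b0[i] + (0.05 + b1[i]) * days +
                                   rnorm(length(days), 0, 0.15)))))
  doses <- data.frame(subject_id = unique(tr$subject_id), day = 1, dose = 3)
  fit <- fit_lmm_log_troughs(cohort_dataset(tr, doses, lloq = 0))
  expect_equal(fit$beta0, 0.9, tolerance = 0.15)
  expect_equal(fit$beta1, 0.05, tolerance = 0.15)
  expect_equal(fit$sigma2_b0, 0.16, tolerance = 0.3)
  expect_equal(fit$sigma2_b1, 0.004, tolerance = 0.3)
  expect_equal(fit$sigma2_e, 0.0225, tolerance = 0.3)
})

test_that("paired endpoint comparison handles identical and shifted data", {
  pk <- data.frame(subject_id = sprintf("S%d", 1:6),
                   c0_max = c(1, 2, 3, 4, 5, 6) + 1,
                   t_c0_max = 2:7, auc_c0_time = 2:7 * 10,
                   avg_accumulation_ratio = rep(1.5, 6),
                   auc_per_dose = 2:7 / 10)
  same <- compare_original_imputed(pk, pk)
  expect_true(all(same$note == "identical"))
  expect_true(all(is.na(same$p_value)))

  shifted <- pk
  shifted$c0_max <- pk$c0_max - 1  # all six differences exactly +1
  cmp <- compare_original_imputed(pk, shifted)
  row <- cmp[cmp$metric == "c0_max", ]
  expect_equal(row$p_value, 0.03125)

  # oracle: exhaustive enumeration of all 2^6 sign assignments
  r <- rank(abs(rep(1, 6)))
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 6)))
  vdist <- as.numeric(signs %*% r)
  v <- sum(r)
  p_exact <- min(1, 2 * min(mean(vdist <= v), mean(vdist >= v)))
  expect_equal(row$p_value, p_exact)
  expect_true(all(cmp$note[cmp$metric != "c0_max"] == "identical"))
})

test_that("gap-free synthetic data make the imputed pipeline a no-op", {
  spec <- synthetic_spec(n_subjects = 8, missingness = 0, schedule = "daily")
  sim <- generate_cohort(spec, seed = 13)
  ds <- sim$dataset
  fit <- fit_lmm_log_troughs(ds)
  filled <- impute_daily(ds, fit)
  expect_false(any(filled$troughs$imputed))
  expect_equal(cohort_pk_surrogates(filled), cohort_pk_surrogates(ds))
  cmp <- compare_original_imputed(cohort_pk_surrogates(ds),
                                  cohort_pk_surrogates(filled))
  expect_true(all(cmp$note == "identical"))
})
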