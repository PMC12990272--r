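test_that("rank-residual Spearman matches the brute-force oracle", {
  set.seed(31)
  for (rep in 1:100) {
    n <- 20
    dose <- runif(n, 50, 150)
    x <- rnorm(n) + 0.01 * dose
    y <- rnorm(n) + 0.01 * dose
    got <- dose_adjusted_spearman(x, y, dose, min_pairs = 16, n_total = n)
    expect_equal(got$statistic, oracle_residual_spearman(x, y, dose),
                 tolerance = 1e-12)
    expect_equal(got$method, "rank_residual_spearman")
    expect_true(got$dose_adjusted)
  }
})

test_that("constant dose reduces exactly to plain Spearman", {
  set.seed(32)
  n <- 20
  x <- rnorm(n)
  y <- rnorm(n)
  dose <- rep(120, n)
  adj <- suppressWarnings(
    dose_adjusted_spearman(x, y, dose, min_pairs = 16, n_total = n))
  plain <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(adj$statistic, unname(plain$estimate), tolerance = 1e-12)

  # strictly increasing relationship: rho exactly 1
  y2 <- exp(x)
  r1 <- suppressWarnings(
    dose_adjusted_spearman(x, y2, dose, min_pairs = 16, n_total = n))
  expect_equal(r1$statistic, 1)
})

test_that("rho is invariant under strictly increasing transforms", {
  set.seed(33)
  n <- 22
  dose <- runif(n, 60, 160)
  x <- rnorm(n); y <- rnorm(n)
  base <- dose_adjusted_spearman(x, y, dose, n_total = n)
  tx <- dose_adjusted_spearman(exp(x), y, dose, n_total = n)
  ty <- dose_adjusted_spearman(x, y^3 + 5 * y, dose, n_total = n)
  expect_equal(tx$statistic, base$statistic, tolerance = 1e-12)
  expect_equal(ty$statistic, base$statistic, tolerance = 1e-12)
  expect_equal(tx$p_value, base$p_value, tolerance = 1e-12)
})

test_that("the completeness rule withholds results below 16 (80%) pairs", {
  set.seed(34)
  x <- c(rnorm(15), rep(NA, 5))
  y <- rnorm(20)
  r <- dose_adjusted_spearman(x, y, runif(20, 50, 100), n_total = 20)
  expect_true(is.na(r$p_value))
  expect_match(r$notes, "insufficient pairs")
  expect_equal(r$n_complete, 15L)
  # constant covariate: flagged, not fabricated
  rc <- dose_adjusted_spearman(rep(2, 20), y, runif(20, 50, 100), n_total = 20)
  expect_match(rc$notes, "constant input")
})

test_that("categorical tests branch on Shapiro and report the partial F", {
  set.seed(35)
  n <- 40
  g <- factor(rep(c("a", "b"), each = n / 2))
  dose <- runif(n, 50, 150)
  y <- rnorm(n, 0, 1) + 0.005 * dose + 3 * (g == "b")  # Delta = 3 sigma
  r <- test_categorical(y, g, dose, min_pairs = 16, n_total = n)
  expect_lt(r$p_value, 0.001)
  expect_match(r$notes, "branch=")

  # oracle: explicit drop-one F from normal equations (normal branch forced)
  yy <- if (grepl("branch=normal", r$notes)) y else rank(y)
  Xf <- cbind(1, g == "b", dose)
  Xr <- cbind(1, dose)
  or <- oracle_partial_f(yy, Xf, Xr)
  expect_equal(r$statistic, or$f, tolerance = 1e-10)
  expect_equal(r$p_value, or$p, tolerance = 1e-10)

  # heavy-tailed outcome takes the rank branch
  yh <- rcauchy(n) + 2 * (g == "b")
  rh <- test_categorical(yh, g, dose, min_pairs = 16, n_total = n)
  expect_match(rh$notes, "branch=rank")
  orh <- oracle_partial_f(rank(yh), cbind(1, g == "b", dose), cbind(1, dose))
  expect_equal(rh$statistic, orh$f, tolerance = 1e-10)

  err <- tryCatch(test_categorical(y, factor(rep("a", n)), dose),
                  troughpk_error = identity)
  expect_equal(err$code, "factor_single_level")
})

test_that("interaction model detects aliasing and reports adjusted R^2", {
  set.seed(36)
  # balanced 2x2: full rank, interaction p reported
  g <- rep(c("AC", "CC"), each = 20)
  a <- rep(rep(c("yes", "no"), each = 10), 2)
  y <- rnorm(40) + (g == "AC") + 2 * (a == "yes")
  full <- interaction_model(y, g, a)
  expect_false(full$aliased)
  expect_true(is.finite(full$interaction_p))

  # collinear pattern: every unexposed subject carries one genotype
  g2 <- c(rep("AC", 10), rep("CC", 6), rep("AC", 4))
  a2 <- c(rep("yes", 16), rep("no", 4))
  y2 <- rnorm(20) + 3 * (g2 == "AC" & a2 == "yes")
  ali <- interaction_model(y2, g2, a2)
  expect_true(ali$aliased)
  expect_true(is.na(ali$interaction_p))
  expect_match(ali$result$notes, "aliased")
  # aliasing flag agrees with an explicit design-matrix rank computation
  X <- cbind(1, g2 == "CC", a2 == "yes", (g2 == "CC") * (a2 == "yes"))
  expect_lt(qr(X)$rank, ncol(X))
  # additive adjusted R^2 still reported, matching the explicit formula
  expect_equal(ali$adj_r2_additive,
               oracle_adj_r2(y2, cbind(1, g2 == "CC", a2 == "yes")),
               tolerance = 1e-10)

  # purely additive model at n = 200: oracle equivalence of adjusted R^2
  g3 <- sample(c("AC", "CC"), 200, replace = TRUE)
  a3 <- sample(c("yes", "no"), 200, replace = TRUE)
  y3 <- rnorm(200) + 1.2 * (g3 == "AC") - 0.8 * (a3 == "yes")
  fit3 <- interaction_model(y3, g3, a3)
  expect_equal(fit3$adj_r2_additive,
               oracle_adj_r2(y3, cbind(1, g3 == "CC", a3 == "yes")),
               tolerance = 1e-10)
})

test_that("combined factor merges levels and degenerates gracefully", {
  g <- c("AC", "AC", "AA", "AA")
  e <- c(TRUE, FALSE, TRUE, TRUE)
  f <- combined_factor(g, e)
  expect_setequal(levels(f), c("AC|cef+", "AC|cef-", "AA|cef+"))

  # canonical collinear cohort: 16 exposed / 4 unexposed, all unexposed AC
  g2 <- c(rep("AC", 10), rep("CC", 10))
  e2 <- c(rep(FALSE, 4), rep(TRUE, 16))
  f2 <- combined_factor(g2, e2)
  expect_setequal(levels(f2), c("AC|cef-", "AC|cef+", "CC|cef+"))

  # constant co-factor: composite is the plain factor in disguise
  set.seed(37)
  y <- rnorm(20) + 2 * (g2 == "AC")
  dose <- runif(20, 50, 150)
  fc <- combined_factor(g2, rep(TRUE, 20))
  expect_equal(nlevels(fc), 2)
  comp <- combined_factor_anova(y, fc, dose, n_total = 20)
  plain <- test_categorical(y, factor(g2), dose, n_total = 20)
  expect_equal(comp$statistic, plain$statistic, tolerance = 1e-12)
  expect_equal(comp$p_value, plain$p_value, tolerance = 1e-12)
})

test_that("the screen enumerates pairs and survives per-pair failures", {
  ds <- make_cohort(function(i, d) 2 + 0.3 * d + 0.2 * i,
                    subjects = sprintf("S%02d", 1:20),
                    genotypes = data.frame(
                      subject_id = sprintf("S%02d", 1:20),
                      origin = "recipient", rsid = "rs2032582",
                      genotype = rep(c("AC", "CC"), 10)))
  pk <- cohort_pk_surrogates(ds)
  cov_sum <- data.frame(subject_id = sprintf("S%02d", 1:20),
                        variable = "ALT", kind = "mean",
                        value = rnorm(20, 40, 10))

  # one continuous + one categorical covariate, two endpoints -> 4 rows
  r <- run_association_screen(ds, pk, cov_sum,
                              endpoints = c("c0_max", "t_c0_max"))
  expect_equal(nrow(r), 4L)
  expect_setequal(r$method[r$covariate == "ALT"], "rank_residual_spearman")

  # no covariates at all -> empty table, header intact
  ds0 <- make_cohort(function(i, d) 2 + 0.3 * d)
  r0 <- run_association_screen(ds0, cohort_pk_surrogates(ds0), NULL)
  expect_equal(nrow(r0), 0L)
  expect_setequal(names(r0), c("outcome", "covariate", "method", "n_complete",
                               "statistic", "p_value", "dose_adjusted",
                               "notes"))

  # dose-normalized endpoints are never dose-adjusted
  rall <- run_association_screen(ds, pk, cov_sum)
  expect_true(all(!rall$dose_adjusted[rall$outcome %in%
                                        c("auc_c0_time", "auc_per_dose")]))
  expect_true(all(rall$dose_adjusted[rall$outcome == "c0_max"]))
})
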