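series_df <- function(days, conc) data.frame(day = days, concentration = conc)

test_that("trapezoidal AUC matches its defining sum and known examples", {
  expect_equal(compute_auc(series_df(1:5, rep(5, 5))), 20)
  expect_equal(compute_auc(series_df(c(1, 3), c(2, 4))), 6)
  expect_equal(compute_auc(series_df(1:6, c(2, 3, 5, 4, 6, 6))), 22)
  expect_error(compute_auc(series_df(3, 5)), "at least 2")

  # oracle: pracma trapezoid on 100 random irregular series
  skip_if_not_installed("pracma")
  set.seed(7)
  for (rep in 1:100) {
    n <- sample(3:20, 1)
    d <- sort(sample(1:40, n))
    cc <- runif(n, 0.5, 12)
    expect_equal(compute_auc(series_df(d, cc)), pracma::trapz(d, cc),
                 tolerance = 1e-12)
  }
})

test_that("AUC is additive over interior days and positively homogeneous", {
  set.seed(8)
  for (rep in 1:25) {
    n <- sample(5:15, 1)
    d <- sort(sample(1:30, n))
    cc <- runif(n, 1, 10)
    s <- series_df(d, cc)
    k <- sample(2:(n - 1), 1)
    expect_equal(compute_auc(s),
                 compute_auc(s[1:k, ]) + compute_auc(s[k:n, ]),
                 tolerance = 1e-12)
    a <- runif(1, 0.1, 5)
    expect_equal(compute_auc(series_df(d, a * cc)), a * compute_auc(s),
                 tolerance = 1e-12)
  }
})

test_that("peak finder matches a brute-force scan and breaks ties early", {
  inc <- series_df(1:8, 1:8)
  expect_equal(compute_peak(inc)$t_c0_max, 8)
  tie <- series_df(c(3, 5), c(7, 7))
  expect_equal(compute_peak(tie)$t_c0_max, 3)

  set.seed(9)
  for (rep in 1:100) {
    d <- sort(sample(1:30, sample(3:25, 1)))
    cc <- round(runif(length(d), 1, 10), 2)
    pk <- compute_peak(series_df(d, cc))
    # linear-scan oracle with earliest-day tie break
    best <- d[min(which(cc == max(cc)))]
    expect_equal(pk$c0_max, max(cc))
    expect_equal(pk$t_c0_max, best)
    # row order never matters after day sorting
    perm <- sample(length(d))
    expect_equal(compute_peak(series_df(d[perm], cc[perm])), pk)
  }
})

test_that("accumulation index is ratio-to-first with unit first ratio", {
  const <- accumulation_index(series_df(1:4, rep(3, 4)))
  expect_equal(const$index$ratio, rep(1, 4))
  expect_equal(const$mean_ratio, 1)
  tri <- accumulation_index(series_df(1:3, c(2, 4, 6)))
  expect_equal(tri$index$ratio, c(1, 2, 3))
  expect_equal(tri$mean_ratio, 2)
  set.seed(10)
  for (rep in 1:20) {
    s <- series_df(1:6, runif(6, 1, 9))
    acc <- accumulation_index(s)
    expect_equal(acc$index$ratio[1], 1)
    # scale invariance
    expect_equal(accumulation_index(series_df(s$day, 3 * s$concentration)),
                 acc, tolerance = 1e-12)
  }
  err <- tryCatch(accumulation_index(series_df(1:2, c(0, 2))),
                  troughpk_error = identity)
  expect_equal(err$code, "index_bad_reference")
})

test_that("Tukey-fence outlier removal matches the hinge oracle", {
  expect_length(remove_outliers(c(1, 2, 3, 4, 5))$removed_idx, 0)
  out <- remove_outliers(c(1, 2, 3, 4, 100))
  expect_equal(out$removed_idx, 5L)
  expect_equal(out$kept, c(1, 2, 3, 4))
  expect_length(remove_outliers(rep(4.2, 6))$removed_idx, 0)

  set.seed(11)
  for (rep in 1:100) {
    x <- rlnorm(sample(5:30, 1), 1, 0.8)
    fe <- oracle_fences(x)
    got <- remove_outliers(x)
    expect_equal(unname(got$fences), fe, tolerance = 1e-10)
    expect_equal(got$removed_idx, which(x < fe[1] | x > fe[2]))
  }
})

test_that("surrogate endpoints assemble consistently from their parts", {
  s <- series_df(1:5, rep(5, 5))
  pk <- compute_pk_surrogates(s, dose_total = 100, subject_id = "A")
  expect_equal(pk$auc_c0_time, 20)
  expect_equal(pk$auc_per_dose, 0.2)
  expect_equal(pk$avg_accumulation_ratio, 1)
  expect_equal(pk$c0_max, 5)
  expect_equal(pk$t_c0_max, 1)

  set.seed(12)
  for (rep in 1:100) {
    d <- sort(sample(1:30, sample(4:20, 1)))
    cc <- runif(length(d), 1, 10)
    td <- runif(1, 20, 200)
    pk <- compute_pk_surrogates(series_df(d, cc), td)
    expect_equal(pk$auc_per_dose * td, pk$auc_c0_time, tolerance = 1e-10)
    expect_true(pk$t_c0_max %in% d)
    expect_equal(pk$c0_max, max(cc))
  }
})

test_that("noiseless synthetic peaks land within one schedule gap of t*", {
  spec <- synthetic_spec(n_subjects = 12, sigma = 0, tau_k = 0.2, tau_S = 0,
                         missingness = 0, beta_geno = 0, beta_abx = 0)
  sim <- generate_cohort(spec, seed = 31)
  pk <- cohort_pk_surrogates(sim$dataset)
  tt <- sim$truth[match(pk$subject_id, sim$truth$subject_id), ]
  gaps <- max(diff(schedule_days(30)))
  expect_true(all(abs(pk$t_c0_max - tt$t_star) <= gaps))
})
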