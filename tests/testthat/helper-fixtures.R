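# Fixture builders and independent oracles shared across test files.
# Oracles are written from the defining formulas, never by calling the
# implementation under test.

# A minimal valid cohort: one row of troughs per (subject, day) from a
# concentration function, constant daily dosing.
make_cohort <- function(conc, subjects = c("A", "B", "C"),
                        days = 1:10, dose = 3, lloq = 0.5, ...) {
  tr <- do.call(rbind, lapply(seq_along(subjects), function(i)
    data.frame(subject_id = subjects[i], day = days,
               concentration = conc(i, days))))
  ds <- do.call(rbind, lapply(subjects, function(s)
    data.frame(subject_id = s, day = days, dose = dose)))
  cohort_dataset(tr, ds, lloq = lloq, ...)
}

# --- Tukey hinge oracle -----------------------------------------------------
# Five-number-summary hinges by the explicit depth formula:
# hinge depth h = (floor((n + 3) / 2)) / 2 on the sorted sample.
oracle_fences <- function(x) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  h <- (floor((n + 3) / 2)) / 2
  lower <- (x[floor(h)] + x[ceiling(h)]) / 2
  upper <- (x[n + 1 - floor(h)] + x[n + 1 - ceiling(h)]) / 2
  iqr <- upper - lower
  c(lower - 1.5 * iqr, upper + 1.5 * iqr)
}

# --- average-rank oracle (explicit ties handling) ---------------------------
oracle_rank <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) r[i] <- sum(x < x[i]) + (1 + sum(x == x[i])) / 2
  r
}

# --- explicit least squares -------------------------------------------------
oracle_ls_residuals <- function(y, X) {
  beta <- solve(t(X) %*% X, t(X) %*% y)
  as.numeric(y - X %*% beta)
}

oracle_pearson <- function(a, b) {
  sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
}

# Rank-residual Spearman oracle: explicit ranks, explicit normal-equations
# residuals on dose, Pearson of the re-ranked residuals.
oracle_residual_spearman <- function(x, y, dose) {
  rx <- oracle_rank(x); ry <- oracle_rank(y)
  X <- cbind(1, dose)
  ex <- oracle_ls_residuals(rx, X)
  ey <- oracle_ls_residuals(ry, X)
  oracle_pearson(oracle_rank(ex), oracle_rank(ey))
}

# Adjusted R^2 from explicit normal equations.
oracle_adj_r2 <- function(y, X) {
  res <- oracle_ls_residuals(y, X)
  n <- length(y); p <- ncol(X)
  1 - (sum(res^2) / (n - p)) / (sum((y - mean(y))^2) / (n - 1))
}

# Partial (drop-one) F for a factor term: RSS comparison of the two
# explicit least-squares fits.
oracle_partial_f <- function(y, X_full, X_reduced) {
  rss_f <- sum(oracle_ls_residuals(y, X_full)^2)
  rss_r <- sum(oracle_ls_residuals(y, X_reduced)^2)
  df1 <- ncol(X_full) - ncol(X_reduced)
  df2 <- length(y) - ncol(X_full)
  f <- ((rss_r - rss_f) / df1) / (rss_f / df2)
  list(f = f, p = stats::pf(f, df1, df2, lower.tail = FALSE))
}
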