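# Dose-adjusted association testing.
#
# Cumulative dose confounds every exposure endpoint, so continuous
# covariate-endpoint associations are tested on rank residuals: both
# variables are rank-transformed (average ranks for ties), each rank vector
# is regressed on total dose by OLS,
#   rank(outcome) = a0 + a1 * total_dose + eta,
# and the Spearman correlation of the two residual vectors is reported — a
# partial rank correlation controlling for cumulative dose. Categorical
# covariates branch on a Shapiro-Wilk normality test of the outcome: normal
# outcomes use lm(outcome ~ factor + dose), non-normal outcomes
# lm(rank(outcome) ~ factor + dose), with the factor's partial
# (drop-one) F test. Dose-normalized endpoints (AUC and AUC/dose) are never
# dose-adjusted. Results are retained only with enough complete pairs
# (default 16, i.e. 80% of a 20-subject cohort).

assoc_row <- function(outcome, covariate, method, n, statistic, p,
                      dose_adjusted, notes = "") {
  data.frame(outcome = outcome, covariate = covariate, method = method,
             n_complete = as.integer(n), statistic = statistic,
             p_value = p, dose_adjusted = dose_adjusted, notes = notes,
             stringsAsFactors = FALSE)
}

# Completeness rule: at least min_pairs complete pairs, or 80% of the
# subjects entering the analysis, whichever is larger.
pairs_threshold <- function(min_pairs, n_total) {
  max(min_pairs, ceiling(0.8 * n_total))
}

#' Dose-adjusted rank-residual Spearman correlation
#'
#' @param x,y aligned numeric vectors (covariate and PK endpoint, one entry
#'   per subject). Outliers should already be removed per variable (set to
#'   `NA`); complete cases are used.
#' @param total_dose aligned total-dose vector, or `NULL` to skip the dose
#'   adjustment (used for dose-normalized endpoints).
#' @param min_pairs minimum complete pairs to report a result (default 16).
#' @param n_total number of subjects entering the analysis, for the 80%
#'   completeness rule; defaults to `length(x)`.
#' @param outcome_name,covariate_name labels carried into the result row.
#' @return one-row data.frame: outcome, covariate, method, n_complete,
#'   statistic (Spearman rho of the residuals), p_value, dose_adjusted,
#'   notes.
#' @export
dose_adjusted_spearman <- function(x, y, total_dose = NULL, min_pairs = 16,
                                   n_total = length(x),
                                   outcome_name = "outcome",
                                   covariate_name = "covariate") {
  adjust <- !is.null(total_dose)
  method <- "rank_residual_spearman"
  cc <- is.finite(x) & is.finite(y)
  if (adjust) cc <- cc & is.finite(total_dose)
  n <- sum(cc)
  thr <- pairs_threshold(min_pairs, n_total)
  if (n < thr)
    return(assoc_row(outcome_name, covariate_name, method, n, NA_real_,
                     NA_real_, adjust,
                     sprintf("insufficient pairs (%d < %d)", n, thr)))
  xs <- x[cc]; ys <- y[cc]
  if (length(unique(xs)) < 2 || length(unique(ys)) < 2)
    return(assoc_row(outcome_name, covariate_name, method, n, NA_real_,
                     NA_real_, adjust, "constant input"))
  rx <- rank(xs); ry <- rank(ys)
  if (adjust) {
    d <- total_dose[cc]
    rx <- stats::residuals(stats::lm(rx ~ d))
    ry <- stats::residuals(stats::lm(ry ~ d))
  }
  ct <- suppressWarnings(stats::cor.test(rx, ry, method = "spearman",
                                         alternative = "two.sided"))
  assoc_row(outcome_name, covariate_name, method, n,
            unname(ct$estimate), ct$p.value, adjust, "")
}

#' Dose-adjusted categorical test with normality branching
#'
#' Shapiro-Wilk decides the branch: outcomes with p >= `shapiro_alpha` are
#' fitted as `lm(outcome ~ factor + total_dose)`, others as
#' `lm(rank(outcome) ~ factor + total_dose)`; the reported statistic is the
#' factor's partial (drop-one) F. Pass `total_dose = NULL` for
#' dose-normalized outcomes.
#'
#' @param outcome numeric endpoint vector (one entry per subject).
#' @param group factor (or coercible) covariate.
#' @param total_dose aligned dose vector or `NULL`.
#' @param min_pairs,n_total completeness rule, as in
#'   [dose_adjusted_spearman].
#' @param shapiro_alpha normality threshold (default 0.05).
#' @param outcome_name,covariate_name labels for the result row.
#' @return one-row data.frame as in [dose_adjusted_spearman]; `notes`
#'   records the Shapiro p and branch taken.
#' @export
test_categorical <- function(outcome, group, total_dose = NULL,
                             min_pairs = 16, n_total = length(outcome),
                             shapiro_alpha = 0.05,
                             outcome_name = "outcome",
                             covariate_name = "factor") {
  adjust <- !is.null(total_dose)
  group <- as.factor(group)
  cc <- is.finite(outcome) & !is.na(group)
  if (adjust) cc <- cc & is.finite(total_dose)
  g <- droplevels(group[cc])
  if (nlevels(g) < 2)
    tpk_stop("factor_single_level",
             "factor '%s' has < 2 non-empty levels among complete cases",
             covariate_name)
  n <- sum(cc)
  if (n < 3)
    tpk_stop("factor_too_few", "need >= 3 complete cases for normality test")
  thr <- pairs_threshold(min_pairs, n_total)
  if (n < thr)
    return(assoc_row(outcome_name, covariate_name, "lm_anova", n, NA_real_,
                     NA_real_, adjust,
                     sprintf("insufficient pairs (%d < %d)", n, thr)))
  y <- outcome[cc]
  if (length(unique(y)) < 2)
    return(assoc_row(outcome_name, covariate_name, "lm_anova", n, NA_real_,
                     NA_real_, adjust, "constant input"))
  sw <- tryCatch(stats::shapiro.test(y)$p.value, error = function(e) NA_real_)
  normal <- !is.na(sw) && sw >= shapiro_alpha
  method <- if (normal) "lm_anova" else "rank_lm_anova"
  yy <- if (normal) y else rank(y)
  dat <- data.frame(yy = yy, g = g)
  form <- yy ~ g
  if (adjust) {
    dat$d <- total_dose[cc]
    form <- yy ~ g + d
  }
  fit <- stats::lm(form, data = dat)
  dr <- stats::drop1(fit, test = "F")
  assoc_row(outcome_name, covariate_name, method, n,
            dr["g", "F value"], dr["g", "Pr(>F)"], adjust,
            sprintf("shapiro_p=%.4g; branch=%s", sw,
                    if (normal) "normal" else "rank"))
}

#' Genotype-antibiotic interaction model with aliasing detection
#'
#' Fits `outcome ~ genotype + antibiotic + genotype:antibiotic` by least
#' squares. When the design matrix is rank deficient (e.g. every
#' antibiotic-unexposed subject carries one genotype, so the interaction
#' column is aliased) the interaction p-value is reported as not applicable
#' with reason `"aliased"`, while the additive model's adjusted R-squared is
#' still reported.
#'
#' @param outcome numeric endpoint.
#' @param genotype,antibiotic aligned factors (or coercibles).
#' @param outcome_name label for the result row.
#' @return list of class `interaction_fit`: `aliased`, `interaction_f`,
#'   `interaction_p` (`NA` when aliased), `adj_r2_additive`, `adj_r2_full`,
#'   `n_complete`, `result` (one-row data.frame in the association-result
#'   schema).
#' @export
interaction_model <- function(outcome, genotype, antibiotic,
                              outcome_name = "outcome") {
  genotype <- as.factor(genotype)
  antibiotic <- as.factor(antibiotic)
  cc <- is.finite(outcome) & !is.na(genotype) & !is.na(antibiotic)
  dat <- data.frame(y = outcome[cc], g = droplevels(genotype[cc]),
                    a = droplevels(antibiotic[cc]))
  # a factor with one observed level is the extreme collinear case: the
  # interaction (and that main effect) is inestimable
  if (nlevels(dat$g) < 2 || nlevels(dat$a) < 2) {
    if (nlevels(dat$g) < 2 && nlevels(dat$a) < 2)
      tpk_stop("interaction_degenerate",
               "genotype and antibiotic are both constant among complete cases")
    keep <- if (nlevels(dat$g) >= 2) "g" else "a"
    additive <- stats::lm(stats::reformulate(keep, "y"), data = dat)
    adj_add <- summary(additive)$adj.r.squared
    res <- assoc_row(outcome_name, "genotype:antibiotic", "interaction_lm",
                     nrow(dat), NA_real_, NA_real_, FALSE,
                     sprintf("aliased (constant co-factor); adj_r2_additive=%.4f",
                             adj_add))
    return(structure(list(aliased = TRUE, interaction_f = NA_real_,
                          interaction_p = NA_real_, adj_r2_additive = adj_add,
                          adj_r2_full = NA_real_, n_complete = nrow(dat),
                          result = res), class = "interaction_fit"))
  }
  X <- stats::model.matrix(~ g * a, dat)
  if (nrow(dat) < ncol(X))
    tpk_stop("interaction_underdetermined",
             "fewer complete cases (%d) than model columns (%d)",
             nrow(dat), ncol(X))
  aliased <- qr(X)$rank < ncol(X)
  additive <- stats::lm(y ~ g + a, data = dat)
  adj_add <- summary(additive)$adj.r.squared
  if (aliased) {
    res <- assoc_row(outcome_name, "genotype:antibiotic", "interaction_lm",
                     nrow(dat), NA_real_, NA_real_, FALSE,
                     sprintf("aliased; adj_r2_additive=%.4f", adj_add))
    out <- list(aliased = TRUE, interaction_f = NA_real_,
                interaction_p = NA_real_, adj_r2_additive = adj_add,
                adj_r2_full = NA_real_, n_complete = nrow(dat), result = res)
  } else {
    full <- stats::lm(y ~ g * a, data = dat)
    dr <- stats::drop1(full, test = "F")
    f <- dr["g:a", "F value"]; p <- dr["g:a", "Pr(>F)"]
    res <- assoc_row(outcome_name, "genotype:antibiotic", "interaction_lm",
                     nrow(dat), f, p, FALSE,
                     sprintf("adj_r2_full=%.4f; adj_r2_additive=%.4f",
                             summary(full)$adj.r.squared, adj_add))
    out <- list(aliased = FALSE, interaction_f = f, interaction_p = p,
                adj_r2_additive = adj_add,
                adj_r2_full = summary(full)$adj.r.squared,
                n_complete = nrow(dat), result = res)
  }
  structure(out, class = "interaction_fit")
}

#' @export
print.interaction_fit <- function(x, ...) {
  cat("<interaction_fit> outcome ~ genotype * antibiotic\n")
  if (x$aliased)
    cat("  interaction aliased (collinear design); additive adj R^2 =",
        sprintf("%.4f\n", x$adj_r2_additive))
  else
    cat(sprintf("  interaction F = %.3f, p = %.4g; full adj R^2 = %.4f\n",
                x$interaction_f, x$interaction_p, x$adj_r2_full))
  invisible(x)
}

#' Combined genotype-antibiotic factor
#'
#' Merges a genotype and an exposure flag into one composite factor with
#' levels `"genotype|cef+"` / `"genotype|cef-"`; subjects missing either
#' component become `NA`, and empty combinations are dropped from the level
#' set.
#'
#' @param genotype character/factor of genotypes.
#' @param exposed logical exposure flags (aligned).
#' @param pos,neg suffixes for exposed / unexposed levels.
#' @return factor of composite levels.
#' @export
combined_factor <- function(genotype, exposed, pos = "cef+", neg = "cef-") {
  genotype <- as.character(genotype)
  lab <- ifelse(exposed, pos, neg)
  lv <- ifelse(is.na(genotype) | is.na(exposed), NA_character_,
               paste(genotype, lab, sep = "|"))
  droplevels(factor(lv))
}

#' Dose-adjusted one-way ANOVA on the combined factor
#'
#' Delegates to [test_categorical] with the composite genotype-antibiotic
#' factor, inheriting the Shapiro branch and the dose-adjustment rule.
#'
#' @inheritParams test_categorical
#' @param composite composite factor from [combined_factor].
#' @return one-row association-result data.frame.
#' @export
combined_factor_anova <- function(outcome, composite, total_dose = NULL,
                                  min_pairs = 16, n_total = length(outcome),
                                  shapiro_alpha = 0.05,
                                  outcome_name = "outcome") {
  r <- test_categorical(outcome, composite, total_dose,
                        min_pairs = min_pairs, n_total = n_total,
                        shapiro_alpha = shapiro_alpha,
                        outcome_name = outcome_name,
                        covariate_name = "genotype|antibiotic")
  r$method <- "combined_factor_anova"
  r
}

# Endpoints that are dose-normalized by definition and therefore never
# adjusted by total dose.
dose_free_endpoints <- c("auc_c0_time", "auc_per_dose")

#' Run the full covariate-endpoint association screen
#'
#' For every (endpoint, covariate) pair: per-variable Tukey-fence outlier
#' removal, then the rank-residual Spearman test for continuous covariates
#' or the normality-branched categorical test for factors, with total-dose
#' adjustment except for the dose-normalized endpoints (`auc_c0_time`,
#' `auc_per_dose`). Per-pair failures become not-applicable rows, never
#' errors.
#'
#' @param dataset a [cohort_dataset] (source of doses, genotypes,
#'   antibiotic exposures).
#' @param pk endpoint table from [cohort_pk_surrogates].
#' @param covariate_summaries long table from
#'   [cohort_covariate_summaries], or `NULL` for none.
#' @param min_pairs completeness rule parameter (default 16).
#' @param shapiro_alpha normality threshold (default 0.05).
#' @param endpoints endpoint columns of `pk` to screen (default all five).
#' @return data.frame of association results, one row per pair: outcome,
#'   covariate, method, n_complete, statistic, p_value, dose_adjusted,
#'   notes.
#' @export
run_association_screen <- function(dataset, pk, covariate_summaries = NULL,
                                   min_pairs = 16, shapiro_alpha = 0.05,
                                   endpoints = c("c0_max", "t_c0_max",
                                                 "auc_c0_time",
                                                 "avg_accumulation_ratio",
                                                 "auc_per_dose")) {
  subjects <- pk$subject_id
  n_total <- length(subjects)
  td <- total_dose(dataset)[subjects]

  # wide continuous covariates, one column per summarized variable
  cont <- list()
  if (!is.null(covariate_summaries) && nrow(covariate_summaries)) {
    for (v in unique(covariate_summaries$variable)) {
      sub <- covariate_summaries[covariate_summaries$variable == v, ]
      cont[[v]] <- sub$value[match(subjects, sub$subject_id)]
    }
  }
  # categorical covariates: genotypes per origin:locus, antibiotics per drug
  cats <- list()
  gt <- dataset$genotypes
  if (nrow(gt)) {
    for (key in unique(paste(gt$origin, gt$rsid, sep = ":"))) {
      parts <- strsplit(key, ":")[[1]]
      sub <- gt[gt$origin == parts[1] & gt$rsid == parts[2], ]
      cats[[key]] <- sub$genotype[match(subjects, sub$subject_id)]
    }
  }
  ab <- dataset$antibiotics
  if (nrow(ab)) {
    for (drug in unique(ab$drug)) {
      sub <- ab[ab$drug == drug, ]
      cats[[paste0("abx:", drug)]] <-
        ifelse(sub$exposed[match(subjects, sub$subject_id)], "yes", "no")
    }
  }

  drop_out <- function(v) {
    v <- as.numeric(v)
    if (sum(is.finite(v)) >= 1) {
      ro <- tryCatch(remove_outliers(v), error = function(e) NULL)
      if (!is.null(ro)) v[ro$removed_idx] <- NA_real_
    }
    v
  }

  rows <- list()
  for (ep in endpoints) {
    y <- drop_out(pk[[ep]])
    dose <- if (ep %in% dose_free_endpoints) NULL else td
    for (v in names(cont)) {
      x <- drop_out(cont[[v]])
      rows[[length(rows) + 1L]] <- tryCatch(
        dose_adjusted_spearman(x, y, dose, min_pairs = min_pairs,
                               n_total = n_total, outcome_name = ep,
                               covariate_name = v),
        error = function(e) assoc_row(ep, v, "rank_residual_spearman",
                                      0L, NA_real_, NA_real_,
                                      !is.null(dose), conditionMessage(e)))
    }
    for (v in names(cats)) {
      rows[[length(rows) + 1L]] <- tryCatch(
        test_categorical(y, cats[[v]], dose, min_pairs = min_pairs,
                         n_total = n_total, shapiro_alpha = shapiro_alpha,
                         outcome_name = ep, covariate_name = v),
        error = function(e) assoc_row(ep, v, "lm_anova", 0L, NA_real_,
                                      NA_real_, !is.null(dose),
                                      conditionMessage(e)))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    assoc_row(character(), character(), character(), integer(),
              numeric(), numeric(), logical(), character())
  rownames(out) <- NULL
  out
}
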