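# Synthetic cohort generator
#
# Emulates the data structure of an early post-transplant tacrolimus TDM
# study: ~20 subjects followed 18-30 days, troughs sampled daily in week 1,
# on alternate days in week 2 and every 3-4 days thereafter, assay LLOQ
# 0.5 ng/mL, rising-then-plateauing trough profiles with an interior maximum,
# and genotype/antibiotic effects that shift accumulation kinetics.
#
# Noiseless trough curve for subject i:
#   mu_i(t) = S_i * (exp(-lambda_i t) - exp(-k_i t)) / f_i(t*_i)
# where f_i(t) = exp(-lambda_i t) - exp(-k_i t) peaks at the closed-form
#   t*_i = log(k_i / lambda_i) / (k_i - lambda_i),
# so S_i is exactly the peak of the noiseless curve and t*_i the analytic
# peak day. Observed troughs are mu_i(t) * exp(eps), eps ~ N(0, sigma^2).
# Accumulation rate: k_i = k0 * exp(beta_geno * 1[rs2032582 AC carrier]
#   + beta_abx * 1[cefoperazone/sulbactam] + u_i), u_i ~ N(0, tau_k^2).
# Scale: S_i = S0 * exp(sum_c gamma_c z_{c,i} + v_i), v_i ~ N(0, tau_S^2),
# with z the standard-normal latents behind the laboratory covariates, so
# exposure magnitude and covariates are genuinely correlated while timing
# effects ride only on k.

default_loci <- data.frame(
  rsid = c("rs1045642", "rs2032582", "rs776746", "rs15524",
           "rs2242480", "rs2246709", "rs4646437"),
  origin = c("recipient", "recipient", "donor", "donor",
             "donor", "donor", "donor"),
  allele1 = c("C", "A", "C", "A", "C", "A", "C"),
  allele2 = c("T", "C", "T", "G", "T", "G", "T"),
  freq1 = c(0.60, 0.45, 0.25, 0.25, 0.70, 0.40, 0.70),
  stringsAsFactors = FALSE)

default_antibiotics <- c(
  cefoperazone_sulbactam = 0.80, ceftazidime = 0.20, cefuroxime = 0.15,
  ceftriaxone_sodium = 0.10, meropenem = 0.15, vancomycin = 0.10,
  cefotaxime_sodium = 0.10)

# Plausible adult post-transplant laboratory scales: location, spread, and
# loading (gamma) of the subject latent on log trough scale S.
default_covariate_model <- data.frame(
  variable = c("ALT", "AST", "total_bilirubin", "hematocrit", "TT", "INR",
               "platelets"),
  mean = c(40, 35, 2.0, 0.32, 17, 1.2, 150),
  sd = c(20, 15, 0.8, 0.04, 2, 0.15, 50),
  gamma = c(0.06, 0.04, 0.05, -0.05, 0, 0, 0),
  stringsAsFactors = FALSE)

#' Construct a synthetic-cohort specification
#'
#' The defaults are the shipped study conditions: 20 subjects, 18-30 day
#' follow-up under the week1-daily / week2-alternate / 3-4-day TDM schedule,
#' LLOQ 0.5 ng/mL, trough scale `S0` = 6 ng/mL, accumulation rate `k0` =
#' 0.30/day and decline rate `lambda0` = 0.035/day (analytic peak around day
#' 8), strong genotype and antibiotic rate effects (`beta_geno` =
#' `beta_abx` = 0.5 on log k), and 10% missingness per scheduled sample.
#'
#' @param n_subjects number of subjects.
#' @param followup_range integer (min, max) follow-up days; each subject's
#'   follow-up is drawn uniformly from this range.
#' @param S0 trough scale, ng/mL: the noiseless peak concentration for a
#'   subject with all latents zero.
#' @param k0 population accumulation rate, 1/day; must exceed `lambda0`.
#' @param lambda0 population decline rate, 1/day.
#' @param beta_geno log-scale multiplier on k for rs2032582 AC carriers.
#' @param beta_abx log-scale multiplier on k under cefoperazone/sulbactam.
#' @param tau_k,tau_S between-subject SD of log k and log S.
#' @param sigma residual log-scale SD of observed troughs.
#' @param missingness probability a scheduled sample is missing.
#' @param schedule `"tdm"` (the week1-daily / week2-alternate / 3-4-day
#'   routine) or `"daily"` (dense daily sampling, used for validation runs).
#' @param lloq assay lower limit of quantification, ng/mL.
#' @param dose_initial initial daily dose, mg/day.
#' @param titration data.frame (day, dose): dose steps applied from `day` on.
#' @param covariate_model data.frame (variable, mean, sd, gamma).
#' @param loci data.frame (rsid, origin, allele1, allele2, freq1).
#' @param antibiotic_probs named exposure probabilities per drug.
#' @param seed default master seed used when [generate_cohort] is called
#'   without one.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_subjects = 20,
                           followup_range = c(18L, 30L),
                           S0 = 6, k0 = 0.30, lambda0 = 0.035,
                           beta_geno = 0.5, beta_abx = 0.5,
                           tau_k = 0.25, tau_S = 0.12, sigma = 0.12,
                           missingness = 0.10, lloq = 0.5,
                           schedule = c("tdm", "daily"),
                           dose_initial = 3,
                           titration = data.frame(day = c(8L, 15L),
                                                  dose = c(3.5, 4)),
                           covariate_model = default_covariate_model,
                           loci = default_loci,
                           antibiotic_probs = default_antibiotics,
                           seed = 1L) {
  schedule <- match.arg(schedule)
  spec <- structure(as.list(environment()), class = "synthetic_spec")
  validate_spec(spec)
  spec
}

validate_spec <- function(spec) {
  if (!(spec$k0 > spec$lambda0 && spec$lambda0 > 0))
    tpk_stop("spec_no_interior_peak",
             "k0 must exceed lambda0 > 0 (k0=%g, lambda0=%g): no interior peak",
             spec$k0, spec$lambda0)
  if (spec$sigma < 0 || spec$tau_k < 0 || spec$tau_S < 0)
    tpk_stop("spec_negative_sd", "sigma, tau_k, tau_S must be >= 0")
  if (spec$missingness < 0 || spec$missingness > 1)
    tpk_stop("spec_probability", "missingness must be in [0, 1]")
  if (any(spec$antibiotic_probs < 0 | spec$antibiotic_probs > 1))
    tpk_stop("spec_probability", "antibiotic probabilities must be in [0, 1]")
  invisible(spec)
}

#' The shipped default synthetic specification
#'
#' Returns the default [synthetic_spec], whose large-sample simulated
#' distributions are checked (softly) against the printed cohort ranges:
#' median observed time-to-maximum-trough inside 3-26 days and maximum
#' troughs predominantly around 5-9 ng/mL.
#'
#' @return a `synthetic_spec`.
#' @export
calibrate_default_spec <- function() synthetic_spec()

#' TDM sampling schedule
#'
#' Week 1 daily (days 1-7), week 2 on alternate days (9, 11, 13), thereafter
#' alternating 3- and 4-day gaps starting with 3 (16, 20, 23, 27, ...),
#' truncated at the follow-up end.
#'
#' @param followup_days last follow-up day.
#' @return integer vector of scheduled sampling days.
#' @export
schedule_days <- function(followup_days) {
  days <- c(1:7, c(9L, 11L, 13L))
  d <- 13L
  gap <- 3L
  while (d + gap <= followup_days) {
    d <- d + gap
    days <- c(days, d)
    gap <- if (gap == 3L) 4L else 3L
  }
  days[days <= followup_days]
}

#' Analytic peak day of the two-exponential trough curve
#'
#' The noiseless curve `exp(-lambda t) - exp(-k t)` has its interior maximum
#' at `log(k/lambda) / (k - lambda)` for `k > lambda > 0`.
#'
#' @param k accumulation rate, 1/day.
#' @param lambda decline rate, 1/day.
#' @return peak day (real, > 0).
#' @export
analytic_peak_day <- function(k, lambda) log(k / lambda) / (k - lambda)

two_exp_curve <- function(t, k, lambda, S) {
  tstar <- analytic_peak_day(k, lambda)
  fmax <- exp(-lambda * tstar) - exp(-k * tstar)
  S * (exp(-lambda * t) - exp(-k * t)) / fmax
}

# Independent sub-seeds per generation component so toggling one component
# leaves the draws of the others unchanged.
stream_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) + stream * 1000003) %% 2147483629)
}

#' Generate a synthetic cohort with known truth
#'
#' Draws genotypes, antibiotic exposures, laboratory covariate series, dose
#' histories and noisy trough profiles under the two-exponential accumulation
#' model, applying the TDM schedule, per-sample missingness and LLOQ
#' censoring. The returned truth table carries each subject's accumulation
#' rate `k`, decline rate `lambda`, scale `S` and analytic peak day
#' `t_star`, plus per-subject sample accounting.
#'
#' @param spec a [synthetic_spec].
#' @param seed master seed; defaults to `spec$seed`. Identical spec + seed
#'   give identical output.
#' @return list with elements `dataset` (a [cohort_dataset]) and `truth`
#'   (data.frame: subject_id, k, lambda, S, t_star, n_scheduled, n_observed,
#'   n_censored, n_missing) plus the effect sizes used.
#' @export
generate_cohort <- function(spec = synthetic_spec(), seed = spec$seed) {
  validate_spec(spec)
  n <- spec$n_subjects
  ids <- sprintf("S%02d", seq_len(n))
  sched <- function(f) {
    if (identical(spec$schedule, "daily")) seq_len(f) else schedule_days(f)
  }

  # --- design stream: genotypes, antibiotics, follow-up lengths ----------
  set.seed(stream_seed(seed, 1))
  followup <- sample(seq(spec$followup_range[1], spec$followup_range[2]),
                     n, replace = TRUE)
  loci <- spec$loci
  geno <- do.call(rbind, lapply(seq_len(nrow(loci)), function(l) {
    a <- ifelse(stats::runif(n) < loci$freq1[l], loci$allele1[l], loci$allele2[l])
    b <- ifelse(stats::runif(n) < loci$freq1[l], loci$allele1[l], loci$allele2[l])
    data.frame(subject_id = ids, origin = loci$origin[l], rsid = loci$rsid[l],
               genotype = normalize_genotype(paste0(a, b)))
  }))
  abx <- do.call(rbind, lapply(names(spec$antibiotic_probs), function(drug) {
    data.frame(subject_id = ids, drug = drug,
               exposed = stats::runif(n) < spec$antibiotic_probs[[drug]])
  }))

  # --- covariate stream: subject latents and measurement series ----------
  set.seed(stream_seed(seed, 2))
  cm <- spec$covariate_model
  z <- matrix(stats::rnorm(n * nrow(cm)), n, nrow(cm),
              dimnames = list(ids, cm$variable))
  cov_rows <- list()
  for (j in seq_len(nrow(cm))) {
    for (i in seq_len(n)) {
      days <- c(0L, sched(followup[i]))
      noise <- stats::rnorm(length(days), 0, 0.4)
      val <- cm$mean[j] + cm$sd[j] * (0.8 * z[i, j] + noise)
      cov_rows[[length(cov_rows) + 1L]] <- data.frame(
        subject_id = ids[i], day = days, variable = cm$variable[j],
        value = round(val, 4))
    }
  }
  covariates <- if (length(cov_rows)) do.call(rbind, cov_rows) else
    empty_covariates()

  # --- trough stream: subject kinetics and residual noise ----------------
  set.seed(stream_seed(seed, 3))
  u <- stats::rnorm(n, 0, spec$tau_k)
  v <- stats::rnorm(n, 0, spec$tau_S)
  is_ac <- ids %in% geno$subject_id[geno$rsid == "rs2032582" &
                                    geno$origin == "recipient" &
                                    geno$genotype == "AC"]
  is_cef <- ids %in% abx$subject_id[abx$drug == "cefoperazone_sulbactam" &
                                    abx$exposed]
  k_i <- spec$k0 * exp(spec$beta_geno * is_ac + spec$beta_abx * is_cef + u)
  S_i <- spec$S0 * exp(as.numeric(z %*% cm$gamma) + v)
  lambda_i <- rep(spec$lambda0, n)

  trough_rows <- list()
  n_sched <- integer(n)
  for (i in seq_len(n)) {
    days <- sched(followup[i])
    n_sched[i] <- length(days)
    eps <- stats::rnorm(length(days), 0, spec$sigma)
    conc <- two_exp_curve(days, k_i[i], lambda_i[i], S_i[i]) * exp(eps)
    trough_rows[[i]] <- data.frame(subject_id = ids[i], day = days,
                                   concentration = round(conc, 3))
  }
  troughs <- do.call(rbind, trough_rows)

  # --- missingness stream -------------------------------------------------
  set.seed(stream_seed(seed, 4))
  keep <- stats::runif(nrow(troughs)) >= spec$missingness
  n_missing <- tapply(!keep, troughs$subject_id, sum)
  troughs <- troughs[keep, , drop = FALSE]

  # --- deterministic dose histories --------------------------------------
  dose_rows <- lapply(seq_len(n), function(i) {
    days <- seq_len(followup[i])
    dose <- rep(spec$dose_initial, length(days))
    if (nrow(spec$titration))
      for (s in seq_len(nrow(spec$titration)))
        dose[days >= spec$titration$day[s]] <- spec$titration$dose[s]
    data.frame(subject_id = ids[i], day = days, dose = dose)
  })
  doses <- do.call(rbind, dose_rows)

  dataset <- cohort_dataset(troughs, doses, covariates, geno, abx,
                            lloq = spec$lloq,
                            provenance = sprintf("synthetic seed=%d", seed))

  n_obs <- tapply(dataset$troughs$subject_id,
                  factor(dataset$troughs$subject_id, levels = ids), length)
  n_cen <- tapply(dataset$censored$subject_id,
                  factor(dataset$censored$subject_id, levels = ids), length)
  truth <- data.frame(
    subject_id = ids, k = k_i, lambda = lambda_i, S = S_i,
    t_star = analytic_peak_day(k_i, lambda_i),
    ac_carrier = is_ac, cefoperazone = is_cef,
    n_scheduled = n_sched,
    n_observed = as.integer(ifelse(is.na(n_obs), 0L, n_obs)),
    n_censored = as.integer(ifelse(is.na(n_cen), 0L, n_cen)),
    n_missing = as.integer(n_missing[ids]))
  list(dataset = dataset, truth = truth,
       effects = list(beta_geno = spec$beta_geno, beta_abx = spec$beta_abx,
                      gamma = stats::setNames(cm$gamma, cm$variable)))
}

#' Read / write a synthetic specification as YAML
#'
#' @param spec a `synthetic_spec`.
#' @param path YAML file path.
#' @return `spec_to_yaml` returns the path invisibly; `spec_from_yaml`
#'   returns a `synthetic_spec`.
#' @export
spec_to_yaml <- function(spec, path) {
  s <- unclass(spec)
  s$titration <- as.list(as.data.frame(spec$titration))
  s$covariate_model <- as.list(as.data.frame(spec$covariate_model))
  s$loci <- as.list(as.data.frame(spec$loci))
  s$antibiotic_probs <- as.list(spec$antibiotic_probs)
  yaml::write_yaml(s, path)
  invisible(path)
}

#' @rdname spec_to_yaml
#' @export
spec_from_yaml <- function(path) {
  s <- yaml::read_yaml(path)
  s$titration <- as.data.frame(s$titration)
  s$covariate_model <- as.data.frame(s$covariate_model)
  s$loci <- as.data.frame(s$loci)
  s$antibiotic_probs <- unlist(s$antibiotic_probs)
  s$followup_range <- as.integer(unlist(s$followup_range))
  do.call(synthetic_spec, s)
}
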