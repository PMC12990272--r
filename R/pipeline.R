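# End-to-end orchestration: simulate (or load) -> impute -> PK endpoints ->
# covariate summaries -> association screen, with a plain-text run log and a
# manifest for reproducibility.

#' Pipeline run configuration
#'
#' @param out_dir output directory for all stage artifacts.
#' @param input_dir directory holding the five cohort CSVs, or `NULL` to
#'   simulate a cohort from `spec`.
#' @param spec a [synthetic_spec] used when `input_dir` is `NULL`.
#' @param seed master seed for the run.
#' @param impute toggle the mixed-model gap-filling stage.
#' @param random_effects random-effects structure for the imputation model.
#' @param min_pairs,shapiro_alpha association-screen parameters.
#' @param init_day treatment-initiation day for covariate baselines.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir, input_dir = NULL, spec = synthetic_spec(),
                       seed = 1L, impute = TRUE,
                       random_effects = "intercept_slope",
                       min_pairs = 16, shapiro_alpha = 0.05, init_day = 1L) {
  structure(list(out_dir = out_dir, input_dir = input_dir, spec = spec,
                 seed = as.integer(seed), impute = impute,
                 random_effects = random_effects, min_pairs = min_pairs,
                 shapiro_alpha = shapiro_alpha, init_day = init_day,
                 version = as.character(utils::packageVersion("troughpk"))),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' Round-trips a [run_config] (including its embedded [synthetic_spec])
#' through a YAML file.
#'
#' @param config a `run_config`.
#' @param path YAML file path.
#' @return `config_to_yaml` returns the path invisibly; `config_from_yaml`
#'   returns a `run_config`.
#' @export
config_to_yaml <- function(config, path) {
  s <- unclass(config)
  s$spec <- if (!is.null(config$spec)) {
    sp <- unclass(config$spec)
    sp$titration <- as.list(as.data.frame(sp$titration))
    sp$covariate_model <- as.list(as.data.frame(sp$covariate_model))
    sp$loci <- as.list(as.data.frame(sp$loci))
    sp$antibiotic_probs <- as.list(sp$antibiotic_probs)
    sp
  }
  s$version <- NULL
  yaml::write_yaml(s, path)
  invisible(path)
}

#' @rdname config_to_yaml
#' @export
config_from_yaml <- function(path) {
  s <- yaml::read_yaml(path)
  if (!is.null(s$spec)) {
    sp <- s$spec
    sp$titration <- as.data.frame(sp$titration)
    sp$covariate_model <- as.data.frame(sp$covariate_model)
    sp$loci <- as.data.frame(sp$loci)
    sp$antibiotic_probs <- unlist(sp$antibiotic_probs)
    sp$followup_range <- as.integer(unlist(sp$followup_range))
    s$spec <- do.call(synthetic_spec, sp)
  }
  do.call(run_config, s)
}

# 32-bit FNV-1a over the serialized config, for the manifest's config hash.
fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(utils::capture.output(utils::str(x)),
                                      collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Run the full trough-PK pipeline
#'
#' Executes the stages in order — cohort acquisition (synthetic generation
#' or CSV load), optional mixed-model daily imputation, surrogate PK
#' endpoints, covariate summaries, association screen, and the combined
#' genotype-antibiotic analysis — writing every stage output, a `run.log`
#' describing decisions taken (normality branches, rows dropped), and a
#' `manifest.json`. Identical config + seed give identical outputs.
#'
#' @param config a [run_config].
#' @return invisibly, the manifest list (files, config hash, seed).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  if (!dir.exists(out) && !dir.create(out, recursive = TRUE, showWarnings = FALSE))
    tpk_stop("io_unwritable", "cannot create output directory %s", out)
  logf <- file.path(out, "run.log")
  cat(sprintf("troughpk %s run, seed %d\n", config$version, config$seed),
      file = logf)
  note <- function(...) cat(sprintf(...), "\n", file = logf, append = TRUE)
  t0 <- Sys.time()
  stage <- function(name, code) {
    s <- Sys.time()
    r <- tryCatch(code, error = function(e) {
      note("stage %s FAILED: %s", name, conditionMessage(e))
      tpk_stop("stage_failure", "stage '%s' failed: %s", name,
               conditionMessage(e))
    })
    note("stage %-11s ok (%.2f s)", name,
         as.numeric(difftime(Sys.time(), s, units = "secs")))
    r
  }

  acquired <- stage("cohort", {
    if (is.null(config$input_dir)) {
      generate_cohort(config$spec, seed = config$seed)
    } else {
      p <- function(f) file.path(config$input_dir, f)
      list(dataset = read_cohort(p("troughs.csv"), p("doses.csv"),
                                 p("covariates.csv"), p("genotypes.csv"),
                                 p("antibiotics.csv")),
           truth = NULL)
    }
  })
  dataset <- acquired$dataset
  truth <- acquired$truth
  write_cohort(dataset, file.path(out, "cohort"))
  if (!is.null(truth)) {
    tw <- truth[c("subject_id", "k", "lambda", "S", "t_star")]
    utils::write.csv(tw, file.path(out, "truth.csv"), row.names = FALSE)
  }
  note("cohort: %d subjects, %d trough obs, %d censored",
       length(cohort_subjects(dataset)), nrow(dataset$troughs),
       nrow(dataset$censored))

  pk_raw <- stage("pk_raw", cohort_pk_surrogates(dataset, use_imputed = FALSE))
  analysis_set <- dataset
  if (config$impute) {
    analysis_set <- stage("impute", {
      fit <- fit_lmm_log_troughs(dataset, config$random_effects)
      note("imputation model: beta0=%.4f beta1=%.5f s2_b0=%.4g s2_b1=%.4g s2_e=%.4g%s",
           fit$beta0, fit$beta1, fit$sigma2_b0, fit$sigma2_b1, fit$sigma2_e,
           if (fit$degenerate) " (degenerate)" else "")
      impute_daily(dataset, fit)
    })
    write_cohort(analysis_set, file.path(out, "cohort_imputed"))
    note("imputed rows added: %d",
         sum(analysis_set$troughs$imputed) - sum(dataset$troughs$imputed))
  }
  pk <- stage("pk", cohort_pk_surrogates(analysis_set, use_imputed = TRUE))
  utils::write.csv(pk, file.path(out, "pk_surrogates.csv"), row.names = FALSE)
  if (config$impute) {
    cmp <- compare_original_imputed(pk_raw, pk)
    utils::write.csv(cmp, file.path(out, "imputation_comparison.csv"),
                     row.names = FALSE)
    for (i in seq_len(nrow(cmp)))
      note("imputation comparison %s: %s", cmp$metric[i],
           if (cmp$note[i] == "identical") "identical"
           else sprintf("Wilcoxon p=%.4g", cmp$p_value[i]))
  }

  covs <- stage("covariates",
                cohort_covariate_summaries(analysis_set, config$init_day))
  utils::write.csv(covs, file.path(out, "covariate_summaries.csv"),
                   row.names = FALSE)

  assoc <- stage("associate",
                 run_association_screen(dataset, pk, covs,
                                        min_pairs = config$min_pairs,
                                        shapiro_alpha = config$shapiro_alpha))
  utils::write.csv(assoc, file.path(out, "associations.csv"),
                   row.names = FALSE)
  for (i in which(assoc$notes != ""))
    note("associate %s ~ %s: %s", assoc$outcome[i], assoc$covariate[i],
         assoc$notes[i])

  combined <- stage("combined", {
    run_combined_analysis(dataset, pk, min_pairs = config$min_pairs,
                          shapiro_alpha = config$shapiro_alpha)
  })
  utils::write.csv(combined, file.path(out, "combined_factor.csv"),
                   row.names = FALSE)

  files <- sort(c(list.files(file.path(out, "cohort"), full.names = FALSE),
                  if (config$impute)
                    paste0("cohort_imputed/",
                           list.files(file.path(out, "cohort_imputed")))))
  manifest <- list(
    seed = config$seed,
    config_hash = fnv1a_hash(unclass(config)[setdiff(names(config), "out_dir")]),
    version = config$version,
    files = sort(setdiff(list.files(out, recursive = TRUE),
                         c("manifest.json"))),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  note("done in %.2f s", manifest$elapsed_s)
  invisible(manifest)
}

#' Combined genotype-antibiotic analysis of time to maximum trough
#'
#' The headline pharmacogenomic analysis: tests the recipient rs2032582
#' genotype-by-cefoperazone/sulbactam interaction on t(C0,max) (reporting
#' the aliasing status and additive adjusted R-squared), then the
#' dose-adjusted one-way ANOVA on the merged genotype-exposure factor.
#'
#' @param dataset a [cohort_dataset] with genotypes and antibiotics.
#' @param pk endpoint table from [cohort_pk_surrogates].
#' @param outcome endpoint name (default `"t_c0_max"`).
#' @param rsid,origin,drug which locus and drug to combine.
#' @inheritParams test_categorical
#' @return data.frame with the interaction row and the combined-factor
#'   ANOVA row.
#' @export
run_combined_analysis <- function(dataset, pk, outcome = "t_c0_max",
                                  rsid = "rs2032582", origin = "recipient",
                                  drug = "cefoperazone_sulbactam",
                                  min_pairs = 16, shapiro_alpha = 0.05) {
  subjects <- pk$subject_id
  gt <- dataset$genotypes
  gt <- gt[gt$rsid == rsid & gt$origin == origin, ]
  geno <- gt$genotype[match(subjects, gt$subject_id)]
  ab <- dataset$antibiotics
  ab <- ab[ab$drug == drug, ]
  exposed <- ab$exposed[match(subjects, ab$subject_id)]
  if (all(is.na(geno)) || all(is.na(exposed)))
    tpk_stop("combined_missing_inputs",
             "genotype %s (%s) or drug %s absent from cohort", rsid, origin,
             drug)
  y <- pk[[outcome]]
  td <- total_dose(dataset)[subjects]
  inter <- interaction_model(y, geno, ifelse(exposed, "yes", "no"),
                             outcome_name = outcome)
  comp <- combined_factor(geno, exposed)
  anova_row <- tryCatch(
    combined_factor_anova(
      y, comp, if (outcome %in% dose_free_endpoints) NULL else td,
      min_pairs = min_pairs, n_total = length(subjects),
      shapiro_alpha = shapiro_alpha, outcome_name = outcome),
    troughpk_error = function(e)
      data.frame(outcome = outcome, covariate = "genotype|antibiotic",
                 method = "combined_factor_anova",
                 n_complete = length(subjects), statistic = NA_real_,
                 p_value = NA_real_, dose_adjusted = FALSE,
                 notes = conditionMessage(e)))
  rbind(inter$result, anova_row)
}
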