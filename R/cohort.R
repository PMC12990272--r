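# Classed conditions so callers can dispatch on machine-readable reason codes.
tpk_stop <- function(code, msg, ...) {
  cond <- structure(
    class = c("troughpk_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1), code = code)
  )
  stop(cond)
}

#' Assemble and validate a cohort dataset
#'
#' A cohort dataset bundles everything the trough-PK pipeline consumes for one
#' study: observed trough concentrations, below-LLOQ censored troughs, daily
#' doses, longitudinal laboratory covariates, recipient/donor SNP genotypes,
#' and per-drug antibiotic exposure flags. Trough rows with concentration
#' below the assay's lower limit of quantification (LLOQ) are moved to the
#' censored table; only quantifiable values enter analyses.
#'
#' @param troughs data.frame with columns `subject_id`, `day` (integer days
#'   since treatment initiation, day 1 = first day of dosing), and
#'   `concentration` (ng/mL). Values below `lloq` are censored automatically.
#' @param doses data.frame with columns `subject_id`, `day`, `dose` (mg).
#' @param covariates data.frame with columns `subject_id`, `day`, `variable`,
#'   `value`. Optional (default empty).
#' @param genotypes data.frame with columns `subject_id`, `origin`
#'   (`"recipient"` or `"donor"`), `rsid`, `genotype` (two-letter allele pair;
#'   alleles are sorted so `"CA"` is stored as `"AC"`). Optional.
#' @param antibiotics data.frame with columns `subject_id`, `drug`, `exposed`
#'   (logical). Optional.
#' @param lloq lower limit of quantification in ng/mL (default 0.5).
#' @param provenance free-text provenance note.
#' @return An object of class `cohort_dataset`: a list with elements
#'   `troughs`, `censored`, `doses`, `covariates`, `genotypes`, `antibiotics`,
#'   `lloq`, `provenance`.
#' @export
cohort_dataset <- function(troughs, doses,
                           covariates = empty_covariates(),
                           genotypes = empty_genotypes(),
                           antibiotics = empty_antibiotics(),
                           lloq = 0.5, provenance = "") {
  troughs <- as.data.frame(troughs)
  doses <- as.data.frame(doses)
  covariates <- as.data.frame(covariates)
  genotypes <- as.data.frame(genotypes)
  antibiotics <- as.data.frame(antibiotics)

  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      tpk_stop("schema_missing_column", "%s: missing required column(s) %s",
               what, paste(miss, collapse = ", "))
  }
  need(troughs, c("subject_id", "day", "concentration"), "troughs")
  need(doses, c("subject_id", "day", "dose"), "doses")
  need(covariates, c("subject_id", "day", "variable", "value"), "covariates")
  need(genotypes, c("subject_id", "origin", "rsid", "genotype"), "genotypes")
  need(antibiotics, c("subject_id", "drug", "exposed"), "antibiotics")

  troughs$subject_id <- as.character(troughs$subject_id)
  troughs$day <- as.integer(troughs$day)
  troughs$concentration <- as.numeric(troughs$concentration)
  doses$subject_id <- as.character(doses$subject_id)
  doses$day <- as.integer(doses$day)
  doses$dose <- as.numeric(doses$dose)
  covariates$subject_id <- as.character(covariates$subject_id)
  covariates$day <- as.integer(covariates$day)
  covariates$variable <- as.character(covariates$variable)
  covariates$value <- as.numeric(covariates$value)
  genotypes$subject_id <- as.character(genotypes$subject_id)
  genotypes$origin <- as.character(genotypes$origin)
  genotypes$rsid <- as.character(genotypes$rsid)
  genotypes$genotype <- normalize_genotype(as.character(genotypes$genotype))
  antibiotics$subject_id <- as.character(antibiotics$subject_id)
  antibiotics$drug <- as.character(antibiotics$drug)
  antibiotics$exposed <- as.logical(antibiotics$exposed)

  if (!"imputed" %in% names(troughs))
    troughs$imputed <- rep(FALSE, nrow(troughs))
  troughs$imputed <- as.logical(troughs$imputed)

  below <- troughs$concentration < lloq
  censored <- troughs[below, c("subject_id", "day", "concentration")]
  troughs <- troughs[!below, , drop = FALSE]

  ord <- order(troughs$subject_id, troughs$day)
  troughs <- troughs[ord, , drop = FALSE]
  rownames(troughs) <- NULL
  censored <- censored[order(censored$subject_id, censored$day), , drop = FALSE]
  rownames(censored) <- NULL
  doses <- doses[order(doses$subject_id, doses$day), , drop = FALSE]
  rownames(doses) <- NULL

  x <- structure(
    list(troughs = troughs, censored = censored, doses = doses,
         covariates = covariates, genotypes = genotypes,
         antibiotics = antibiotics, lloq = lloq, provenance = provenance),
    class = "cohort_dataset")
  validate_cohort(x)
  x
}

empty_covariates <- function()
  data.frame(subject_id = character(), day = integer(),
             variable = character(), value = numeric())
empty_genotypes <- function()
  data.frame(subject_id = character(), origin = character(),
             rsid = character(), genotype = character())
empty_antibiotics <- function()
  data.frame(subject_id = character(), drug = character(),
             exposed = logical())

# Unordered allele pairs: sort the two letters so "CA" == "AC".
normalize_genotype <- function(g) {
  vapply(g, function(s) {
    paste(sort(strsplit(s, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Validate a cohort dataset's invariants
#'
#' Checks the structural invariants: strictly increasing unique trough days
#' per subject, all retained concentrations at or above the LLOQ, every
#' trough subject having a dose history, unique keys in every component
#' table. Violations raise a classed condition (`troughpk_error`) whose
#' `code` field is a machine-readable reason.
#'
#' @param x a `cohort_dataset`.
#' @return `x`, invisibly, if valid.
#' @export
validate_cohort <- function(x) {
  stopifnot(inherits(x, "cohort_dataset"))
  tr <- x$troughs
  if (anyNA(tr$concentration) || anyNA(tr$day))
    tpk_stop("trough_na", "troughs contain missing day or concentration")
  if (any(tr$day < 1))
    tpk_stop("trough_day_range", "trough days must be >= 1 (day 1 = first dosing day)")
  dup <- duplicated(tr[c("subject_id", "day")])
  if (any(dup))
    tpk_stop("trough_duplicate_day", "duplicate (subject, day) trough rows: %s",
             paste(unique(tr$subject_id[dup]), collapse = ", "))
  if (any(tr$concentration < x$lloq))
    tpk_stop("trough_below_lloq", "retained trough concentration below LLOQ")
  if (nrow(x$doses)) {
    if (any(x$doses$dose < 0))
      tpk_stop("dose_negative", "doses must be >= 0")
    ddup <- duplicated(x$doses[c("subject_id", "day")])
    if (any(ddup))
      tpk_stop("dose_duplicate_day", "duplicate (subject, day) dose rows")
  }
  orphan <- setdiff(unique(tr$subject_id), unique(x$doses$subject_id))
  if (length(orphan))
    tpk_stop("trough_without_dose",
             "subject(s) with troughs but no dose history: %s",
             paste(orphan, collapse = ", "))
  cdup <- duplicated(x$covariates[c("subject_id", "variable", "day")])
  if (any(cdup))
    tpk_stop("covariate_duplicate", "duplicate (subject, variable, day) covariate rows")
  gdup <- duplicated(x$genotypes[c("subject_id", "origin", "rsid")])
  if (any(gdup))
    tpk_stop("genotype_duplicate", "duplicate (subject, origin, locus) genotype rows")
  adup <- duplicated(x$antibiotics[c("subject_id", "drug")])
  if (any(adup))
    tpk_stop("antibiotic_duplicate", "duplicate (subject, drug) exposure rows")
  invisible(x)
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat("<cohort_dataset>\n")
  cat(sprintf("  subjects:     %d\n", length(cohort_subjects(x))))
  cat(sprintf("  trough obs:   %d (+ %d censored < LLOQ %.2g ng/mL)\n",
              nrow(x$troughs), nrow(x$censored), x$lloq))
  cat(sprintf("  dose rows:    %d\n", nrow(x$doses)))
  cat(sprintf("  covariates:   %d rows, %d variables\n",
              nrow(x$covariates), length(unique(x$covariates$variable))))
  cat(sprintf("  genotypes:    %d rows; antibiotics: %d rows\n",
              nrow(x$genotypes), nrow(x$antibiotics)))
  invisible(x)
}

#' Subjects present in a cohort
#' @param x a `cohort_dataset`.
#' @return character vector of subject ids (sorted).
#' @export
cohort_subjects <- function(x) {
  sort(unique(c(x$troughs$subject_id, x$doses$subject_id)))
}

#' Total administered dose per subject
#'
#' Sum of all dose records over the monitoring window, the adjustment
#' covariate of the dose-adjusted association tests.
#'
#' @param x a `cohort_dataset`.
#' @return named numeric vector, mg, one entry per dosed subject.
#' @export
total_dose <- function(x) {
  if (!nrow(x$doses)) return(stats::setNames(numeric(0), character(0)))
  td <- tapply(x$doses$dose, x$doses$subject_id, sum)
  stats::setNames(as.numeric(td), names(td))
}

#' One subject's trough series
#' @param x a `cohort_dataset`.
#' @param subject subject id.
#' @return data.frame (day, concentration, imputed), days strictly increasing.
#' @export
trough_series <- function(x, subject) {
  s <- x$troughs[x$troughs$subject_id == subject,
                 c("day", "concentration", "imputed")]
  rownames(s) <- NULL
  s
}

csv_schemas <- list(
  troughs = c("subject_id", "day", "concentration_ng_ml"),
  doses = c("subject_id", "day", "dose_mg"),
  covariates = c("subject_id", "day", "variable", "value"),
  genotypes = c("subject_id", "origin", "rsid", "genotype"),
  antibiotics = c("subject_id", "drug", "exposed")
)

read_csv_checked <- function(path, cols, what) {
  if (!file.exists(path))
    tpk_stop("io_missing_file", "%s file not found: %s", what, path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  miss <- setdiff(cols, names(df))
  if (length(miss))
    tpk_stop("schema_missing_column", "%s (%s): missing column(s) %s",
             what, path, paste(miss, collapse = ", "))
  df
}

num_col <- function(df, col, path) {
  v <- suppressWarnings(as.numeric(df[[col]]))
  bad <- which(is.na(v) & !(df[[col]] %in% c("", "NA")))
  if (length(bad))
    tpk_stop("schema_bad_value",
             "%s: non-numeric '%s' at data line(s) %s",
             path, col, paste(bad + 1L, collapse = ", "))
  v
}

#' Read a cohort from its five canonical CSV files
#'
#' Trough rows with concentration below the LLOQ are recorded in the
#' censored table and excluded from the analysis observations. Malformed
#' rows are reported with their line numbers.
#'
#' @param trough_path CSV `subject_id,day,concentration_ng_ml`.
#' @param dose_path CSV `subject_id,day,dose_mg`.
#' @param covariate_path CSV `subject_id,day,variable,value` (optional).
#' @param genotype_path CSV `subject_id,origin,rsid,genotype` (optional).
#' @param antibiotic_path CSV `subject_id,drug,exposed` (optional).
#' @param lloq lower limit of quantification, ng/mL.
#' @return a validated [cohort_dataset].
#' @export
read_cohort <- function(trough_path, dose_path,
                        covariate_path = NULL, genotype_path = NULL,
                        antibiotic_path = NULL, lloq = 0.5) {
  tr <- read_csv_checked(trough_path, csv_schemas$troughs, "troughs")
  troughs <- data.frame(
    subject_id = tr$subject_id,
    day = as.integer(num_col(tr, "day", trough_path)),
    concentration = num_col(tr, "concentration_ng_ml", trough_path))
  if ("imputed" %in% names(tr))
    troughs$imputed <- tr$imputed %in% c("TRUE", "true", "1")

  ds <- read_csv_checked(dose_path, csv_schemas$doses, "doses")
  doses <- data.frame(
    subject_id = ds$subject_id,
    day = as.integer(num_col(ds, "day", dose_path)),
    dose = num_col(ds, "dose_mg", dose_path))

  covariates <- empty_covariates()
  if (!is.null(covariate_path)) {
    cv <- read_csv_checked(covariate_path, csv_schemas$covariates, "covariates")
    covariates <- data.frame(
      subject_id = cv$subject_id,
      day = as.integer(num_col(cv, "day", covariate_path)),
      variable = cv$variable,
      value = num_col(cv, "value", covariate_path))
  }
  genotypes <- empty_genotypes()
  if (!is.null(genotype_path)) {
    gt <- read_csv_checked(genotype_path, csv_schemas$genotypes, "genotypes")
    genotypes <- gt[csv_schemas$genotypes]
  }
  antibiotics <- empty_antibiotics()
  if (!is.null(antibiotic_path)) {
    ab <- read_csv_checked(antibiotic_path, csv_schemas$antibiotics, "antibiotics")
    antibiotics <- data.frame(
      subject_id = ab$subject_id, drug = ab$drug,
      exposed = ab$exposed %in% c("TRUE", "true", "1", "yes", "Yes"))
  }

  cohort_dataset(troughs, doses, covariates, genotypes, antibiotics,
                 lloq = lloq,
                 provenance = sprintf("read_cohort(%s)", trough_path))
}

#' Write a cohort to its five canonical CSV files
#'
#' Censored below-LLOQ rows are written back into `troughs.csv` alongside
#' observed rows, so a read/write round trip conserves every record.
#'
#' @param x a `cohort_dataset`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a manifest data.frame (file, rows).
#' @export
write_cohort <- function(x, out_dir) {
  validate_cohort(x)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    tpk_stop("io_unwritable", "cannot create output directory %s", out_dir)

  tr_out <- rbind(
    data.frame(subject_id = x$troughs$subject_id, day = x$troughs$day,
               concentration_ng_ml = x$troughs$concentration,
               imputed = x$troughs$imputed),
    if (nrow(x$censored))
      data.frame(subject_id = x$censored$subject_id, day = x$censored$day,
                 concentration_ng_ml = x$censored$concentration,
                 imputed = FALSE))
  tr_out <- tr_out[order(tr_out$subject_id, tr_out$day), , drop = FALSE]
  files <- list(
    troughs.csv = tr_out,
    doses.csv = data.frame(subject_id = x$doses$subject_id,
                           day = x$doses$day, dose_mg = x$doses$dose),
    covariates.csv = x$covariates,
    genotypes.csv = x$genotypes,
    antibiotics.csv = x$antibiotics)
  manifest <- data.frame(file = names(files),
                         rows = vapply(files, nrow, integer(1)),
                         row.names = NULL)
  for (nm in names(files))
    utils::write.csv(files[[nm]], file.path(out_dir, nm),
                     row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
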