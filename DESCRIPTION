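Package: troughpk
Title: Trough-Concentration Pharmacokinetics for Early Post-Transplant
    Therapeutic Drug Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for non-compartmental analysis of longitudinal trough
    concentrations collected under routine therapeutic drug monitoring in
    the first post-transplant month. Computes trough-derived surrogate
    accumulation endpoints (maximum trough, time to maximum trough,
    trapezoidal trough AUC, average accumulation ratio, AUC per total
    dose), fills intermittent sampling gaps with a linear mixed model on
    log concentrations, reduces longitudinal laboratory covariates to
    per-subject summaries (mean, baseline, smooth-trajectory mean
    derivative), and tests covariate-endpoint associations with
    dose-adjusted rank-residual Spearman correlations, normality-branched
    dose-adjusted linear models, and combined genotype-antibiotic factor
    ANOVA. Ships a synthetic cohort generator with analytically known peak
    times for validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    lme4,
    mgcv,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    nlme,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
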