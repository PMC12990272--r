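---
title: "Trough-based accumulation pharmacokinetics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trough-based accumulation pharmacokinetics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Tacrolimus after liver transplantation is managed by therapeutic drug
monitoring (TDM): pre-dose (trough, C0) whole-blood concentrations drawn on
a routine schedule — daily in the first week, on alternate days in the
second, every 3–4 days thereafter — with an assay lower limit of
quantification (LLOQ) of 0.5 ng/mL. Intensive post-dose sampling is not
available, so classical single-dose absorption metrics (Cmax, Tmax,
dosing-interval AUC) are undefined. What the trough series does support is
a description of *accumulation*: how fast troughs build up, where they
plateau, and how much cumulative exposure a patient sees in the first
post-transplant month.

`troughpk` computes five per-subject surrogate endpoints from such series:

* **C0,max** — the highest observed trough (ng/mL);
* **t(C0,max)** — the day (1-based, day 1 = first dosing day) on which it
  occurs, a surrogate for time to steady-state attainment;
* **AUC(C0,time)** — the linear-trapezoid area under the trough-versus-day
  curve over the monitoring window (ng·day/mL), a *partial cumulative
  exposure*, not a dosing-interval AUC;
* **average accumulation ratio** — the mean of each trough divided by the
  subject's first measurable trough (the first ratio is exactly 1);
* **AUC/total dose** — cumulative exposure normalized by the total
  administered dose (mg) over the window.

and then tests their associations with longitudinal laboratory covariates,
SNP genotypes (ABCB1 in recipients, CYP3A-region loci in donors) and
antibiotic co-medication, controlling for cumulative dose throughout.

## Gap filling with a linear mixed model

The TDM schedule leaves the trough series gappy. To obtain one
concentration per day, `fit_lmm_log_troughs()` fits

$$\log C_{ij} = (\beta_0 + b_{0i}) + (\beta_1 + b_{1i})\,d_{ij} + e_{ij},$$

with independent subject-level random intercept and slope
(diagonal covariance) and residual $e_{ij}$, estimated by REML.
`impute_daily()` fills each subject's missing integer days — from their
first to their last observed day, never extrapolating — with
$\exp(\text{subject-specific prediction})$, i.e. the BLUP line, without
back-transform bias correction: imputed values are model predictions used
as plug-ins, not unbiased estimators of the mean concentration. Observed
values are never altered (asserted by test).

Choices a user should know about:

* The fixed/random structure is an assumption, not a fact of the data; it
  is switchable to intercept-only (`random_effects = "intercept"`), the
  more stable choice for very small cohorts. The diagonal (independent)
  intercept–slope covariance is the default because a free correlation is
  weakly identified with ~20 subjects on ~14 sampling days.
* Fitting uses `lme4::lmer` with the `bobyqa` optimizer. Boundary fits
  (a variance component estimated at zero) are legitimate answers, not
  errors. A cohort lying exactly on one shared line puts the REML optimum
  on the $\sigma_e \to 0$ boundary where the criterion degenerates; this
  case is detected and answered with the OLS line and zero variance
  components, flagged `degenerate`.
* Endpoints before and after imputation are compared per metric with a
  two-sided paired Wilcoxon signed-rank test. For 12 or fewer non-zero
  paired differences the p-value comes from exhaustive enumeration of all
  sign patterns, which stays exact when absolute differences are tied
  (imputation often shifts a metric by identical amounts across subjects;
  the standard exact algorithm refuses ties, and a normal approximation at
  n ≤ 12 is not an acceptable substitute). All-zero differences are
  reported as `"identical"`, not as a fabricated p-value.

AUC may be computed on the imputed daily grid or on the raw irregular
observations; both modes are exposed (`use_imputed`), since the two are
systematically different quantities on a curved profile and a user should
choose deliberately.

## Covariate summarization

Each longitudinal laboratory variable (ALT, AST, total bilirubin,
hematocrit, TT, INR, platelets, ...) is reduced to three per-subject
scalars: the monitoring-period mean; the baseline (suffix `_baseline`); and
a smooth-trajectory mean derivative (suffix `_trajectory`). The trajectory
slope fits a penalized cubic regression spline (`mgcv::gam`, basis
dimension `min(10, n_obs - 1)`, REML smoothness selection), predicts on 200
evenly spaced points spanning the observed day range, and averages the 199
forward differences. On a uniform grid that mean telescopes exactly to
$(\hat y_{200} - \hat y_1)/(d_{\max} - d_{\min})$, an identity the code
asserts internally — so the summary is best read as "smoothed net change
per day".

Baseline is defined as the latest measurement at or before the treatment
initiation day (default day 1; day-0 draws are pre-initiation labs), else
the first available measurement. Whether "baseline" should mean
pre-operative or day-of-initiation is genuinely ambiguous in routine data;
the at-or-before-initiation rule is the package's documented choice.
Series with fewer than 4 points fall back to the OLS line slope (flagged
`ols`); exactly constant series short-circuit to slope 0 rather than
asking the smoother to estimate a zero-variance curve.

## Association testing

Cumulative dose drives every exposure endpoint, so continuous
covariate–endpoint associations use a **rank-residual partial Spearman**:
both variables are rank-transformed (average ranks for ties), each rank
vector is regressed by OLS on total dose,
$\mathrm{rank}(y) = \alpha_0 + \alpha_1\,\text{dose} + \eta$, and the
Spearman correlation of the two residual vectors is reported. When total
dose is constant this reduces *exactly* to the plain Spearman correlation
(asserted by test). The statistic is invariant under strictly increasing
transforms of either variable.

Categorical covariates branch on a Shapiro–Wilk test of the outcome at
$\alpha = 0.05$ (a conventional threshold): normal outcomes are fitted as
`lm(outcome ~ factor + dose)`, non-normal ones as
`lm(rank(outcome) ~ factor + dose)`. The reported statistic is the
factor's *partial* (drop-one) F. With the factor entered first, sequential
and partial tests coincide when dose is balanced across factor levels;
partial is reported because it does not depend on term order.

Two rules apply uniformly across the screen:

* **Dose-normalized endpoints** (`auc_c0_time`, `auc_per_dose`) are never
  dose-adjusted — the AUC/dose ratio is dose-normalized by definition, and
  adjusting the AUC while also offering its dose ratio would double-count.
* **Completeness**: a result is reported only with at least
  `max(min_pairs, ceil(0.8 n))` complete pairs (default `min_pairs = 16`,
  i.e. 80% of a 20-subject cohort). The rule is applied to categorical
  tests as well as correlations; whether that uniformity is required is an
  open interpretation, so it is a visible parameter, and withheld results
  carry an explicit reason (`insufficient pairs`, `constant input`) rather
  than a p-value.

Tukey-fence outlier removal (`boxplot.stats()` hinges, fences at hinge ±
1.5·IQR) is applied per variable across subjects before each analysis.
No multiple-testing correction is applied; the output table carries
everything needed for the user's own FDR control downstream.

### Genotype–antibiotic interaction and the combined factor

`interaction_model()` fits
`outcome ~ genotype + antibiotic + genotype:antibiotic` and checks the
design matrix rank explicitly. In small pharmacogenomic cohorts the
interaction is often inestimable — the canonical pattern being every
antibiotic-unexposed subject carrying the same genotype — and in that case
the interaction p-value is reported as not applicable with reason
`aliased`, while the additive model's adjusted R² is still returned. A
factor that is entirely constant among complete cases is treated as the
extreme of the same phenomenon. `combined_factor()` then merges the two
variables into one composite factor (levels `"AC|cef+"` etc., empty
combinations dropped) whose dose-adjusted one-way ANOVA
(`combined_factor_anova()`, delegating to the categorical test above) is
the estimable summary of the joint effect.

## The synthetic cohort generator

There is no public patient-level dataset with this structure, so the
package ships a generator, `generate_cohort()`, that emulates the study
design the analysis assumes — it is first-class, tested code, not a
fixture. Each subject's noiseless trough curve is a scaled two-exponential

$$\mu_i(t) = S_i\,\frac{e^{-\lambda_i t} - e^{-k_i t}}
                     {e^{-\lambda_i t^*_i} - e^{-k_i t^*_i}},
\qquad t^*_i = \frac{\ln(k_i/\lambda_i)}{k_i - \lambda_i},$$

which rises, peaks at the closed-form day $t^*_i$ (requiring
$k_i > \lambda_i > 0$), and declines slowly — matching the empirically
observed rising-then-plateauing trough profiles with interior maxima. The
closed-form peak gives every recovery test an analytic truth. No claim is
made that patients follow this curve; it is generator machinery chosen so
the truth is exact.

Effects are placed deliberately: genotype (rs2032582 AC carriage) and
cefoperazone/sulbactam exposure multiply the accumulation rate
$k_i = k_0\exp(\beta_{geno}\mathbf{1}[AC] + \beta_{abx}\mathbf{1}[cef] + u_i)$
— shifting *timing* (earlier $t^*$, since $dt^*/dk < 0$) — while
laboratory-covariate latents load on the scale
$S_i = S_0\exp(\sum_c \gamma_c z_{ci} + v_i)$ — shifting *magnitude* — so
the two effect channels are separable in recovery tests. Observed troughs
are $\mu_i(t)e^{\varepsilon}$, $\varepsilon \sim N(0, \sigma^2)$, sampled
on the TDM schedule ("every 3–4 days" implemented as alternating 3- and
4-day gaps starting with 3), truncated at a per-subject follow-up drawn
uniformly from 18–30 days, thinned by per-sample missingness, and censored
below the LLOQ. Four independent RNG streams (design, covariates, troughs,
missingness) derive from the master seed, so toggling one component leaves
the others' draws unchanged; identical spec + seed gives byte-identical
output.

Shipped defaults (the study conditions the tests exercise): 20 subjects;
$S_0 = 6$ ng/mL, $k_0 = 0.30$/day, $\lambda_0 = 0.035$/day (population
analytic peak near day 8, within the 3–26-day range reported for observed
peak days in this setting); between-subject SDs $\tau_k = 0.25$,
$\tau_S = 0.12$; residual $\sigma = 0.12$; strong kinetic effects
$\beta_{geno} = \beta_{abx} = 0.5$ on $\log k$, consistent with both
factors being reported as significant; cefoperazone/sulbactam exposure
probability 0.80 (16/20 in the motivating cohort); 10% missingness per
scheduled sample; daily dose 3 mg stepped to 3.5 and 4 mg at days 8 and 15
(illustrative only — real titration is TDM-guided, which the generator
deliberately does not model, as feedback would make every downstream
quantity endogenous to the monitoring itself). `calibrate_default_spec()`
exposes these defaults; the test suite checks softly, at n = 2000, that
the simulated median observed peak day falls inside 3–26 days and that
maximum troughs are predominantly within about 5–9 ng/mL.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: dose-adaptation feedback, physiological
covariate dynamics (labs are rescaled Gaussian latents, not organ-function
trajectories), assay error structure beyond log-normal noise,
non-stationary kinetics (e.g. recovering CYP3A activity), or dropout
mechanisms other than independent missingness.

## Numerical choices and problem sizes

* Ties in `t(C0,max)`: broken to the earliest day — deterministic, and
  reads as "time to first attainment" of the maximum.
* The average accumulation ratio includes the first time point (ratio
  exactly 1); excluding it would shift every mean by a known amount and is
  trivially undone by the user.
* Outlier fences use the five-number-summary (Tukey hinge) convention, not
  type-7 quantiles, to match the `boxplot.stats()` reference exactly.
* Validation failures raise classed conditions with machine-readable
  `code` fields (`trough_duplicate_day`, `trough_without_dose`, ...).
* Statistical calibration checks run at 60 subjects per replicate, 600
  replicates for type-I error and 200 null covariates for screen
  uniformity; power checks run at 200 subjects, 100 replicates; mixed-model
  recovery at 200 subjects over 20 seeds. These sizes are the package's
  chosen compromise between Monte-Carlo resolution (binomial SE ≈ 0.9
  percentage points at 600 replicates) and a test suite that runs in
  minutes. Calibration of the rank-ANCOVA and residual-rank tests is
  asymptotic — each loses a degree of freedom to the dose regression that
  the reference distribution ignores — which is why calibration is checked
  at 60 subjects rather than 20.

## Known limitations

* The linear-in-day log-trough mixed model is a working approximation; a
  subject whose profile is strongly curved will be filled along a straight
  log-scale line between observations.
* Below-LLOQ values are excluded from analysis (retained as censored
  metadata). With an LLOQ of 0.5 ng/mL and troughs an order of magnitude
  higher this is almost always inconsequential, but no substitution method
  (LLOQ/2, censored likelihood) is offered.
* Endpoints are treated as known quantities in the association stage;
  imputation uncertainty is not propagated (single model-based fill-in).
* The day-valued endpoint `t(C0,max)` is heavily tied; its rank-based
  p-values have a coarser permutation support than the continuous
  endpoints.
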