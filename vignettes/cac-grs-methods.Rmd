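---
title: "Methods: CAC genetic risk scores, calcification models and added predictive value"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CAC genetic risk scores, calcification models and added predictive value}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cacgrs)
```

# The problem

A genetic risk score for coronary artery calcification (CAC) aggregates a
small number of GWAS lead SNPs — eleven loci in the motivating setting —
into one number per person, `raw = sum(w_i * d_i)`, where `d_i` is the
dosage of the effect allele (0–2, possibly fractional after imputation) and
`w_i` the per-allele GWAS effect size. Because calcified plaque is an
intermediate phenotype of coronary artery disease (CAD), such a score is a
candidate predictor of CAD itself, potentially complementary to broad
CAD polygenic scores built from millions of variants. This package
implements the evaluation chain for that idea: score construction,
case-control association, calcified-plaque-area modelling, and a bootstrap
test of added predictive value over conventional risk factors.

# Score construction

**Harmonization.** A scoring file records an effect and an other allele per
variant; a genotype file records REF/ALT. When file ALT equals the effect
allele the dosage is used as-is; when file REF equals the effect allele the
dosage is flipped to `2 - d`. Palindromic pairs (A/T, C/G) are dropped by
default rather than strand-inferred from frequencies: with only eleven
variants a single silent strand error shifts the score materially, so we
prefer losing a variant to silently corrupting the sum (an
`drop_palindromic = FALSE` override exists). All exclusions are returned
with machine-readable reasons. Harmonization is idempotent, and a
consistent REF/ALT swap in the source (with `d -> 2 - d`) leaves the
aligned matrix unchanged; both properties are tested.

**Missing dosages** are imputed with the per-variant mean (twice the
estimated allele frequency) before scoring, the common choice in polygenic
scoring: it keeps every sample scoreable and is unbiased for the score mean.
`n_variants_used` records per sample how many variants contributed a
non-imputed dosage.

**Standardization** uses the sample SD (`n - 1` denominator, the default in
mainstream statistical software) and is computed within each cohort, because
per-SD odds ratios are reported per cohort. A zero-variance score is an
error, not a silent zero division.

**Quantile bins.** Association by score interval uses four quartile
intervals (five quantile edges), the lowest interval being the reference.
Intervals are left-open/right-closed except the first, so a value equal to
an internal edge goes to the lower bin — a deterministic, documented
tie-break. Ties heavy enough to empty a bin raise an error suggesting fewer
bins. Bin membership is invariant under standardization (a monotone map).

# CAD association models

Three nested logistic regressions mirror the conventional structure:

* model 1: score + age + sex + BMI;
* model 2 (clinical flavor): score + age + sex + smoking + HDL and total
  cholesterol + systolic blood pressure + hypertension treatment + genotype
  PCs; the autopsy flavor, where lipids and blood pressure do not exist,
  uses score + age + sex + BMI + smoking + hypertension treatment + PCs;
* model 3: model 2 + a second polygenic score.

Fitting is binomial IRLS (`stats::glm.fit`) — a standard model deserves the
standard fitter — behind a surface that validates the design (both outcome
classes present, full rank after complete-case filtering), detects perfect
separation, and reports per term the log-odds estimate, SE, `exp(beta)` with
a 95% Wald interval `exp(beta ± 1.96 SE)` and a two-sided Wald p-value. Wald
rather than profile-likelihood intervals match the symmetric intervals
conventional in this literature. Missing covariates are handled by
complete-case analysis (no imputation), so `n_used` shrinks when
questionnaire covariates are sparse; this matches how reduced denominators
are reported in the motivating setting. Sex is coded as a male = 1
indicator. Statin usage is accepted as an optional extra covariate
(`include_statin`), off by default: whether it belongs in the adjustment set
is ambiguous in the source analyses, so the package exposes the toggle
rather than guessing.

**Genotype principal components.** Variant columns are centered by `2f` and
scaled by `sqrt(2 f (1 - f))` (the Patterson convention); PCs are the
leading left singular vectors, sign-fixed so each component's
largest-magnitude loading is positive. One design point matters in
practice: PCs must be computed from a genome-wide panel (here the wide
metaGRS stand-in genotypes), not from the handful of scored SNPs — the
score is a linear combination of those SNPs, so their PCs are partially
collinear with it and absorb part of its effect. The pipeline therefore
prefers the wide panel whenever one is loaded.

**Stratified reruns** subset by sex or by age 40 and drop the stratifying
variable from the design (it is constant within stratum). A failed stratum
(for example one outcome class only) is recorded as an error object without
aborting the others; strata under 100 samples carry a low-power warning
rather than being dropped.

# Beta regression of calcified-plaque area

Calcified-area percentages in the LAD and RCA are proportions in [0, 100].
Dividing by 100, the model is `y ~ Beta(mu*phi, (1-mu)*phi)` with
`logit(mu) = x'beta` and a single constant precision `phi > 0` (no
dispersion covariates: the target analyses report a single OR column).
`exp(beta)` is reported per term and labelled an OR by convention; it is a
multiplicative effect on the mean-proportion odds `mu/(1-mu)`, not a
case-control odds ratio.

**Optimization.** Maximum likelihood in `(beta, log phi)` by Newton steps
with step-halving, so the log-likelihood never decreases (the trace is kept
and tested); the fall-back direction is the gradient when the Hessian is
not usable. Starting values are least squares on `logit(y)` for `beta` and
a method-of-moments estimate for `phi`; convergence is declared when the
log-likelihood changes by less than 1e-10 (at most 200 iterations).
Standard errors come from the inverse observed information at the optimum;
the asymptotic covariance of `beta` is invariant to parameterizing the
precision as `log phi`. Degenerate fits (`phi` collapsing to 0 or
diverging) are flagged, not hidden. The implementation is cross-checked in
the test suite against an independent maximum-likelihood implementation
(`glmmTMB` with a beta family) and against a brute-force grid search on a
tiny instance.

**Boundary values.** Exact 0% and 100% areas occur in real morphometry but
lie outside the beta support. When present, every observation is compressed
with `y' = (y (n - 1) + 0.5) / n` (the Smithson–Verkuilen transform; 0.5 is
a fixed point). When the outcome contains no boundary values the model is
fitted on the raw proportions: the compression is not free — with outcome
mass piled near a boundary (small `mu`, small `phi`) it visibly attenuates
coefficients at autopsy-cohort sample sizes — so it is applied only when
the support problem it solves actually arises. The number of
boundary-adjusted observations is reported with the fit.

# Added predictive value

The primitive is the rank-based (Mann–Whitney) AUC,
`(#{case > control} + 0.5 #{ties}) / (n_case * n_control)`, computed with
midranks and tested against exhaustive pair counting.

`bootstrap_delta_auc()` quantifies what a score adds over a reference
covariate set: per replicate, draw `n` rows with replacement, split 70/30,
fit reference and augmented logistic models on the training part, and
record both AUCs on the held-out part. The comparison is paired — both
models see the same resample and split — which is what makes the
per-replicate ΔAUC meaningful. Headline AUCs are the means of the
per-replicate held-out AUCs (the summary statistic is a documented choice),
and the empirical p-value is the proportion of replicates with ΔAUC below
zero, exact zeros counted at half weight (a measure-zero event for
continuous predictors). The split is a simple random split by default, with
a `stratify_split` option; the resample is drawn before the split.
Replicate-level seeds are derived deterministically from the top-level
seed and are prefix-stable, so increasing `B` extends rather than
reshuffles the replicate sequence. Replicates whose split leaves one
outcome class are dropped and counted; more than 5% such failures is an
error.

**Calibration of the empirical p-value.** This p-value is conservative
rather than uniform under the null: the spread of ΔAUC across replicates is
dominated by split-and-resample noise, which does not shrink with the
(null) signal, so null p-values concentrate near 0.5 instead of spreading
uniformly. Our calibration tests therefore assert what the procedure
actually guarantees — the null rejection rate at 0.05 stays within the
nominal binomial band (in practice well below it) — and the power
simulations show the procedure still separates a genuine per-SD effect of
1.5 at a few thousand samples. Users should read small p-values as strong
evidence, but not interpret mid-range p-values on a uniform scale.

`undersample_balance()` discards random majority-class rows until classes
match, for rechecking conclusions free of the case/control imbalance.

# The synthetic cohort generator

The generator is first-class, tested code, and defines the study conditions
for every recovery and calibration test:

* **Genotypes**: 11 independent scored SNPs (plus a wide stand-in panel,
  default 1000 variants, for the second score and for PCs) under
  Hardy–Weinberg equilibrium, frequencies uniform on [0.05, 0.5], optional
  clipped Gaussian dosage noise mimicking imputation. Weights are Gaussian,
  rescaled so the raw score has unit SD in expectation
  (`sum(w^2 2f(1-f)) = 1`).
* **Covariates**: age ~ N(62, 10) clipped to [18, 95] years, 72% male,
  BMI ~ N(27.5, 4) kg/m², SBP ~ N(140, 20) mmHg, total cholesterol ~
  N(208, 40) and HDL ~ N(38, 12) mg/dL, smoking 60%, hypertension treatment
  58%, statin 48% — anchored to the clinical characteristics of the cohorts
  this design emulates. The autopsy flavor omits lipids/BP and masks
  smoking and hypertension jointly (questionnaire non-response) for an
  exact count of samples, 65.5% by default.
* **Outcomes**: the CAD linear predictor is exactly the model-2 structure —
  `alpha + log(1.4) z + covariate effects` — with `alpha` calibrated by
  bisection (tolerance 1e-4) so the mean probability hits the target case
  fraction (70/30 by default). Making the generative model coincide with
  the fitted model keeps the per-SD OR a well-defined estimand of model 2;
  the second score has a null effect by default (`per_sd_or_meta = 1`) for
  the same reason. Calcified areas are Beta-distributed with
  `logit(mu) = -1.8 + log(1.78) z + 0.5 z_age` and `phi = 5`, anchored to
  the reported calcification effect size and observed area ranges; stenosis
  is a noisy monotone transform of calcification whose only purpose is to
  exercise the threshold-based case definition (stenosis >= 50%,
  inclusive) — no biological fidelity is claimed for it.
* **Presets**: `luric` (clinical, n = 2742, ~70% cases), `tvs` (clinical,
  n = 133, ~74% cases), `tsds` (autopsy, n = 660 with coronary morphometry
  for 622 and questionnaire covariates for 228, ~53% cases).

What the generator does **not** emulate: linkage disequilibrium between
variants (the scored SNPs are independent lead SNPs, but a real wide panel
has LD), population stratification and admixture (PCs in simulation adjust
for pure noise), age-dependent calcification onset, informative
missingness, and genotyping/imputation artefacts beyond symmetric dosage
noise. Passing recovery tests therefore demonstrate correctness of the
estimators under the stated generative model, not robustness to those
real-data complications.

# Numerical and testing choices

* Logistic IRLS tolerance 1e-10, 100 iterations; separation flagged when
  coefficients diverge with fitted probabilities at machine bounds.
* Beta regression convergence |Δ log-likelihood| < 1e-10, 200 iterations;
  numerical Hessians by central differences of the analytic gradient
  (step 1e-5).
* Quantile edges use the default empirical quantile definition (type 7);
  with 1000 continuous draws the four bins hold exactly 250 samples each.
* Scores and phenotype tables are written at full precision (17 significant
  digits) so write-then-read round-trips are bit-identical.
* Test problem sizes: parameter recovery at n = 3000 (CAD, 200 replicates)
  and n = 600 (calcification, 200 replicates); bootstrap calibration with
  100 outer runs at B = 200, n = 1500 under the null and n = 3000 for
  power; oracle checks on 100–500 random small instances. These sizes give
  Monte-Carlo error comfortably inside the asserted bands while keeping the
  default test run short.

# Known limitations

* The bootstrap ΔAUC p-value is conservative (see above); it is an
  empirical tail proportion, not a calibrated uniform p-value.
* The Smithson–Verkuilen compression, while standard, attenuates
  coefficients when the outcome mass sits near a boundary; with many exact
  zeros a zero-inflated beta model (out of scope here) is the more faithful
  likelihood.
* Complete-case analysis assumes missingness unrelated to outcome given
  covariates; with questionnaire-style missingness of two thirds, the
  effective sample and power drop accordingly, as the autopsy preset makes
  visible.
* Palindromic variants are dropped, never strand-inferred; a score
  containing many A/T or C/G sites will lose them.
* The real eleven-SNP weights live in the source supplementary material and
  are not redistributed here; all shipped weight files are synthetic
  stand-ins of the same shape.
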