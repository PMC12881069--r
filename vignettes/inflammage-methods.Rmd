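---
title: "Methods: dietary inflammation, systemic inflammation, and the brain age gap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dietary inflammation, systemic inflammation, and the brain age gap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`inflammage` implements an epidemiological analysis chain linking the
inflammatory potential of diet to accelerated brain aging, with a synthetic
cohort generator that makes every stage testable when the underlying cohort
data are access-controlled. This vignette documents the models, the tunable
parameters, the numerical choices, and what the synthetic validation does and
does not establish.

## The scores

### Dietary Inflammatory Index (DII)

Each dietary parameter $i$ (a nutrient, compound or food) carries a
literature-derived inflammatory effect weight $w_i$ (negative =
anti-inflammatory) and a global reference mean $\mu_i$ and SD $\sigma_i$ of
daily intake. For a participant's mean daily intake $x_i$,

$$ z_i = \frac{x_i - \mu_i}{\sigma_i}, \qquad c_i = 2\,\Phi(z_i) - 1, \qquad
\mathrm{DII} = \sum_i c_i\, w_i , $$

where $\Phi$ is the standard-normal CDF. The centered percentile $c_i \in
(-1, 1)$ makes the index zero for a diet at the global mean of every
parameter and bounds it by $\sum_i |w_i|$. The index construction leaves
"centered percentile" underspecified; we use the normal-CDF mapping of the
original index, which is what makes DII $= 0$ at the global mean. Scoring on
an available subset of parameters (e.g. 31 of 45) is permitted behind an
explicit `allow_missing` flag with a warning and no re-weighting; the subset
used is never hard-coded.

Quality control precedes scoring: an assessment is kept only if its energy
intake is plausible (600–3500 kcal/day for females, 800–4200 for males,
bounds inclusive because the exclusion rule is strictly outside them), a
participant is excluded only when *no* assessment survives, and nutrients
are averaged over the surviving assessments before one DII is computed per
participant. The four conventional groups cut at $-2$, $0$ and $+2$ index
units. Stability between first and later assessments is summarized by a
Pearson correlation and Bland–Altman limits of agreement
($\bar d \pm 1.96\,s_d$).

### INFLA-score

Four markers of low-grade systemic inflammation — C-reactive protein, white
blood cell count, platelet count, and the neutrophil-to-lymphocyte ratio —
are each ranked against decile cut points of a reference distribution
(sample-internal by default; exportable for reuse on subsets). Deciles 1–4
score $-4..-1$, deciles 7–10 score $+1..+4$, and deciles 5–6 score 0 — the
middle-decile zero is implied by the published $-16..+16$ range rather than
stated, and we record it as an inference. Ties at a cut point fall into the
lower decile (a deterministic rule; the source does not state one). The
INFLA-score is the sum over the four markers, so it is invariant to any
monotone transformation of a marker column.

## Brain age and its bias correction

Brain age is learned from imaging-derived phenotypes (IDPs) on a *healthy*
subset — participants free of stroke, type 2 diabetes, long-term
illness/disability/frailty, and fair-or-poor self-rated health — because
brain age should match chronological age in healthy aging. The subset is
split 4:1 (round-half-away-from-zero, seeded shuffle) into training and
validation. IDP standardization constants come from the training rows only
and are applied to all rows; columns with zero training SD are dropped with
a warning. Rows with any missing IDP are excluded up front and counted.

The model zoo is a (predictor × feature-selection) grid: L1-penalized
linear regression, gradient-boosted trees, and support-vector regression,
each with either no feature selection or recursive feature elimination with
cross-validation. Hyperparameters are tuned by a bounded, seeded random
search with training-internal cross-validation — a deterministic, desk-scale
replacement for Bayesian optimization; the selection mechanism, lowest mean
absolute error (MAE) on the validation set, is unchanged and is computed on
raw (uncorrected) predictions. The default grid is the L1-linear cell alone,
which in our synthetic regime is both the fastest and the winning cell, as
is typical for high-dimensional linear age signals.

Age predictions regress toward the training mean, overpredicting young and
underpredicting old ages. Regressing raw training predictions on
chronological age, $\hat y = \alpha\,\mathrm{age} + \beta$, the corrected
prediction is

$$ \text{corrected} = \frac{\text{raw} - \beta}{\alpha}. $$

The published formula's bracketing, "[original brain age − β/α]", is read as
$(\text{raw} - \beta)/\alpha$: subtracting the intercept *then* dividing by
the slope is the only reading under which corrected training predictions
regress on age with slope 1 and intercept 0, and that calibration identity
is enforced by test at $10^{-8}$. The brain age gap is
$\mathrm{BAG} = \text{corrected} - \text{age at scan}$; positive values mean
an older-looking brain.

## Association, stratification, least-squares means

Associations of DII (continuous, and as groups 2–4 versus group 1) with BAG
are ordinary least squares with two adjustment sets: *basic* (age, sex,
race, education, Townsend deprivation) and *multivariable* (adding energy
intake, BMI, smoking, physical activity, CVD, type 2 diabetes, hypertension,
and the Alzheimer's polygenic risk score). Confidence intervals use
t-quantiles with $n - p$ degrees of freedom (indistinguishable from normal
quantiles at these sample sizes). Categorical covariates use reference-cell
coding (group 1, never-smoker, low activity, female, non-carrier, low
tertile). No multiplicity adjustment is applied; estimates are reported
as-is. Rank-deficient designs are an error naming the collinear columns,
never a silent drop. Baseline age is the default age adjustment (the choice
between baseline and scan age is ambiguous in the source design; it is a
switch, `age_var`).

Least-squares means per DII group are model predictions averaged over the
observed covariate rows (equivalently, evaluated at covariate means — the
model is linear), with delta-method standard errors.

Stratified analyses refit the model within strata of a modifier (age group
at 60, PRS tertile, APOE ε4 carrier status, sex, BMI category, waist risk),
dropping from the covariate list the variable the modifier is derived from
(e.g. the continuous PRS within PRS tertiles). Continuous age deliberately
*stays* in the age-stratified fits: stratification at 60 is coarse and
residual age confounding within a stratum is real. Interaction is tested in
the pooled model by a joint F test on the exposure × modifier product terms.

## Mediation

The mediation of the DII–BAG association by the INFLA-score uses the linear
product-of-coefficients decomposition on a single jointly listwise-deleted
row set: with mediator model $M = a\,X + \gamma' C$ and outcome model
$Y = c'X + b\,M + \delta' C$,

$$ \mathrm{ACME} = ab, \qquad \mathrm{ADE} = c', \qquad
\text{total} = c' + ab, $$

an identity that holds *exactly* per sample (and per bootstrap replicate) —
it is asserted at $10^{-10}$ in the tests. Inference is a nonparametric
case-resampling bootstrap with percentile intervals; for linear models
without exposure–mediator interaction this estimand coincides with the
quasi-Bayesian formulation, and the exact decomposition identity is why the
percentile bootstrap was chosen. No exposure–mediator interaction term is
included. Because the inflammation markers are drawn at baseline, the DII
entering mediation is computed from the baseline assessment only.

The proportion mediated, $\mathrm{ACME}/\text{total}$, is a ratio whose
sampling distribution is heavy-tailed whenever the total effect is not well
separated from zero — published cohort estimates of this quantity come with intervals as wide as
$(-0.21, 0.49)$. Two consequences in this package: bootstrap replicates with
a degenerate total (below `degenerate_tol`) are excluded from the
proportion's interval and counted (more than 10% triggers an instability
flag), and simulation studies summarize the proportion as the ratio of the
mean ACME to the mean total across seeds (a ratio of means), not the mean of
per-seed ratios, which has no finite expectation in this regime.

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes, with
known truth, so that parameter recovery is checkable end to end.

* **Diet.** A latent "diet inflammatory tendency" $D_i$ (unit normal,
  mildly confounded with age and sex) loads on every dietary parameter with
  the sign of its weight; intakes are log-normal around the reference means
  with the reference CVs, so single-assessment z-scores are standardized by
  construction. The loading default (0.3) was chosen once so that the DII
  spans roughly $-6..+5.5$ with SD $\approx 1.9$, matching the observed
  spread of the index in large cohorts; `nutrient_sd_log` (default 0.25) is
  the within-person assessment-to-assessment log-scale SD. Participants
  carry 1–5 assessments across a baseline cycle (24%) and four online
  cycles (45–55% each); the `baseline_only` scheme, used for mediation
  studies, gives exactly one baseline assessment. Energy intake is
  log-normal around ~2050 kcal and decreases with $D_i$ (pro-inflammatory
  diets report lower energy), leaving a realistic ~1% of assessments
  outside the plausibility bounds.
* **True DII** is computed by scoring the generated intakes with the exact
  scoring code the analysis uses — there is no approximation gap between
  planted and recoverable diet scores.
* **Inflammation.** A latent inflammation variable
  $L = a_L \cdot \mathrm{DII} + \varepsilon$ (with $a_L = 0.025$, chosen so
  the realized INFLA-on-DII slope is ~0.2 score units per DII unit, the
  order reported in cohort studies) drives all four markers with realistic
  marginals (log-normal CRP around 1.3 mg/L, WBC ~6.9, platelets ~252,
  NLR ~2.2). The INFLA-score is then computed by the package's own decile
  scorer.
* **Outcome.** $\mathrm{BAG} = c'\,\mathrm{DII} + b\,S + \text{group
  shifts} + \gamma' X + \varepsilon$ with residual SD 4 years — a typical
  brain-age residual scale, which makes recovery of a 0.07 y/unit effect at
  $n = 20{,}000$ borderline-significant, the regime of interest. The
  mediator coefficient $b$ is *calibrated*: the implied
  exposure-to-mediator slope is $a_L \cdot E[\mathrm{d}S/\mathrm{d}L]$,
  where the derivative factor is the projection slope of the realized
  INFLA-score on the (approximately normal) latent — a quantity identified
  to about 1% even at $n \approx 4{,}400$ because the score-latent
  correlation is strong — and $b$ is set so that the planted ACME/total
  equals `prop_mediated_true` in expectation; $c'$ carries the remainder.
  (Calibrating against the noisy realized DII-to-score regression instead
  would plant seed-dependent, occasionally explosive $b$ values.) Realized
  parameters are stored with the truth table. Covariate effects on BAG are linear in exactly the terms the
  adjusted models contain, so a correctly specified fit is unbiased for the
  planted effect. Group-shift mode (`group_effects`, optionally overridden
  in the older stratum by `group_effects_older`) plants contrasts directly
  on the DII groups; group-2 shifts, for which no published
  estimate is available, default to plausible monotone values (0.13 pooled; 0.10
  middle-aged / 0.20 older).
* **Imaging.** Each IDP is `loading × true brain age + noise`, loadings
  uniform on (0.2, 1), noise SD 10 (per-IDP age correlations ~0.2–0.5,
  typical of structural and diffusion phenotypes); columns carry the
  six-modality labels of the full 1,079-feature schema, proportionally
  scaled to the configured count. True brain age is scan age plus true BAG,
  exactly. Missingness is off by default and injected only to test
  complete-case behavior.
* **Health flags** (stroke 10%, T2D history ~6%, long-standing illness
  ~40%, fair/poor self-rated health ~25%, age-graded) give a
  minority-healthy regime (~35–40% healthy), so the brain-age model trains
  on a few thousand rows at $n = 20{,}000$ — the published workflow's
  scale. Published exclusion counts for such cohorts do not
  determine a unique healthy fraction, so these prevalences are the
  package's own choice.

**What the synthetic validation shows, and what it does not.** Recovery on
these cohorts demonstrates that the estimators are unbiased and calibrated
*under the generating model*: linear effects, Gaussian noise, correctly
specified adjustment, missingness completely at random, IDPs that are clean
linear readouts of one latent. Real cohort data violate all of these in
degree — nonlinear age effects, selection into imaging substudies,
measurement error in diet far beyond log-normal within-person noise,
residual confounding. Passing tests certify the machinery, not the
epidemiology.

## Numerical choices and degenerate inputs

* Quantiles (deciles, tertiles, bootstrap percentiles) use R's default
  type-7 definition; ranks use "smallest k with value ≤ cut point k", ties
  to the lower bin.
* The 4:1 split size is `round(0.8 n)` half-away-from-zero, so 4,355 splits
  as 3,484/871.
* The LASSO path disables early deviance-based termination
  (`fdev = 0`) so that near-noiseless signals can reach an effectively
  unpenalized fit; the λ grid extends to `lambda.min.ratio = 1e-6`.
* Bias correction refuses slopes within $10^{-8}$ of zero; standardization
  refuses (drops, with a warning) zero-variance training columns; Pearson
  correlation on zero-variance input is reported `NA`, not an error.
* The doubly heterozygous APOE diplotype (C/T at both SNPs) cannot be
  phased from genotypes and is flagged ambiguous (`NA`), never guessed.
* All randomness is locally seeded (`with_seed`) and restores the caller's
  RNG state; two runs with equal configuration are byte-identical.

## Study sizes used by the validation suite

The calibration tests run 20 seeded cohorts of $n = 20{,}000$ with 200
IDPs for effect recovery (continuous 0.07 y/unit; group-4 contrast 0.50 y;
age-heterogeneous contrasts 0.49/0.87 y), and 20 cohorts of $n = 4{,}439$
baseline-assessment participants with 1,000 bootstrap replicates for
mediation recovery at a planted mediated fraction of 0.08. The reporting
script (`scripts/acceptance.R`) uses 30 cohorts for the effect studies and
40 for the mediation study: the per-seed estimators are unbiased, so extra
seeds only tighten the study-level mean. 200 IDPs (the
full schema scaled proportionally across modalities) preserves the
many-feature regime while keeping each end-to-end run to a few seconds;
recovery is invariant to the feature count well before that point because
the combined IDP signal already pins true brain age to ~1 year.

## Known limitations

* The packaged DII reference is a synthetic placeholder; published weights
  and global intake statistics are a drop-in CSV
  (`name, weight, global_mean, global_sd`) supplied by the user.
* Mediation assumes sequential ignorability and linearity; no sensitivity
  analysis for unmeasured mediator–outcome confounding is provided, and no
  exposure–mediator interaction is modeled.
* The healthy-subset rule is the boolean-AND of four flags; cohort-specific
  diagnosis-code screens are upstream of this package.
* Tree/SVR models persist only in memory (no portable serialization); the
  linear winner's coefficients and constants are plain data.
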