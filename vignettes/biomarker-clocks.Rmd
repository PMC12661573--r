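---
title: "Modelling biomarker clocks: thresholds, onset ages, and downstream timing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling biomarker clocks: thresholds, onset ages, and downstream timing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biomclock)
```

## The problem

In preclinical Alzheimer's disease, pathology accumulates for a decade or
more before symptoms. Longitudinal biomarkers — amyloid PET (cortical DVR),
plasma p-tau217 (pg/mL), regional tau PET (SUVR), and cognitive composites —
change at different points along this timeline. Two questions drive the
analyses this package implements:

1. **When does an individual's biomarker become abnormal?** Given sparse,
   noisy longitudinal measurements, estimate the age at which each
   participant's biomarker first crossed a positivity threshold (their
   *biomarker onset age*), and hence their *biomarker-positive time* at any
   visit (visit age minus onset age; negative before onset).
2. **Which biomarker clock best explains downstream change?** Re-expressing
   tau PET accumulation and cognitive decline as functions of age,
   amyloid-positive time, or p-tau217-positive time, which time
   operationalization explains the most variance?

`biomclock` provides the full pipeline: data-driven positivity thresholds,
accumulation-curve modelling and onset estimation, onset-timing comparisons,
mixed-effects model comparison, and delta-method estimates of the average
time from one biomarker's onset to another's positivity — together with a
synthetic-cohort generator so that every stage can be validated against
known ground truth.

## Data-driven positivity thresholds (two-step GBTM)

Thresholds are derived from the data rather than imposed. Step one fits
group-based trajectory modelling (GBTM): a finite mixture of
polynomial-in-age mean trajectories with shared Gaussian residual variance,
with class membership at the participant level, estimated by EM with
k-means-style initialization and multiple random restarts (`gbtm()`). The
log-likelihood is asserted non-decreasing at every EM iteration, and a
collapsed class triggers a refit with one class fewer. Ages are mean-centred
before fitting so a group's intercept is its typical level; the number of
groups can be fixed or selected by BIC (`gbtm_select()`, participants as the
effective sample size).

Step two takes the lowest-level ("non-accumulating") group, trims
participants with any observation at or above the group intercept plus two
standard errors, and defines

> threshold = non-accumulating intercept + 95th percentile of the
> within-person SDs of the retained non-accumulators,

i.e. a level that ordinary measurement noise around a stable baseline
exceeds only rarely. The percentile is the linear-interpolation (type-7)
sample quantile; the choice is recorded in the output object.

**A design choice worth flagging.** "Two standard errors" is ambiguous: the
intercept's *estimation* SE shrinks as $1/\sqrt{n}$ and at cohort scale sits
a hair above the group mean, so trimming against it discards nearly every
member of the group (any single noisy observation trips the cut) and
selection-biases the retained within-person SDs downward. We therefore trim
against the model's *residual SD* by default — the cut then means "no
observation beyond ordinary measurement scatter" and retains ~95% of truly
stable participants in simulation. The strict estimation-SE reading remains
available (`identify_nonaccumulators(se_rule = "intercept_se")`), and the
rule used is recorded in the threshold object.

Positivity itself is strict: a participant is positive when the value at
their most recent observation exceeds the threshold (`classify_positivity()`).

## SILA: from rates to a curve to onset ages

Sampled iterative local approximation (SILA) assumes the biomarker follows
an autonomous accumulation law $dv/dt = r(v)$: the rate depends on the level
reached, not on calendar age. The implementation (`sila()`):

1. **Rates.** Each participant with ≥ 2 observations contributes one point:
   their OLS slope of value on age, located at their mean observed value
   (`estimate_rates()`).
2. **Rate-versus-value curve.** Points are averaged in 40 equal-width value
   bins (≥ 3 participants per bin; sparse bins filled by interpolation
   between occupied neighbours), smoothed by a 3-bin moving mean, and
   clamped at a strictly positive floor (`rate_floor`, default $10^{-4}$
   units/yr) so integration can traverse sub-threshold plateaus
   (`sample_rate_curve()`).
3. **Integration.** Forward Euler with step `dt` (default 0.05 yr) from the
   anchor (time 0, value = threshold), forward to the upper and backward to
   the lower domain bound (the 2.5th–97.5th percentiles of observed values,
   extended to include the threshold). Time zero on the curve *is* the
   positivity threshold crossing (`integrate_curve()`). Under a constant
   rate Euler is exact; under smooth laws the error is $O(dt)$ (the tests
   verify the error halves when `dt` halves).
4. **Onset estimation.** Each participant's *reference observation* — their
   first observation after crossing the threshold if ever observed positive,
   otherwise their last observation — is aligned to the curve:
   positive time = curve time at the reference value (monotone linear
   interpolation, terminal-slope extrapolation with a flag beyond the curve),
   and **onset age = reference age − positive time** (`estimate_onset()`).

The subtraction deserves a note: one common statement of the rule adds the
positive time to the observation age, but with a first-positive reference
observation only subtraction places onset in the observed past; both
conventions describe the same alignment and we implement the internally
consistent one. Negative positive-times (sub-threshold references) yield
projected *future* onset ages.

Model fit is summarized by `concentration_rmse()` (RMSE of observed values
against the curve value implied by each participant's onset) and validated
against observed converters: `validate_converters()` compares each
estimated onset age with the midpoint of the last-negative and
first-positive visit ages, reporting the mean difference with a
normal-theory 95% CI.

**Known limitation — early-onset bias.** Because the reference observation
is *selected* for exceeding the threshold, its measurement error is
conditionally positive for near-threshold references, which biases onset
ages early by a fraction of (noise SD)/(accumulation rate) — roughly half a
year under realistic settings, and somewhat more under strongly curved
(logistic) laws where a participant's OLS slope averages over curvature.
The converter-midpoint validation exhibits the same early shift. This is a
property of the reference rule itself, not of the integration, and is left
visible rather than corrected.

## Onset timing across biomarkers

`build_timing_records()` joins two onset tables and computes the onset delta
(p-tau217 onset age − amyloid onset age) for participants positive on both
biomarkers at their last observation; others are `indeterminate`. Deltas
within ±2 years (inclusive) are `coincident`, larger ones `A_first`,
smaller `ptau_first`. Pearson correlations relate onset ages to the delta
(`correlate_onset_with_delta()`), and onset ages are contrasted across sex
or APOE-ε4 carriage with Welch's t-test (`compare_onset_by_group()` — the
unequal-variance form, recorded in the output, since group variances have
no reason to match).

## Comparing biomarker clocks with mixed models

`fit_lmm()` fits `outcome ~ time (+ time²) + covariates` with correlated
random intercepts and time slopes per participant, by **maximum likelihood**
(not REML): AICc and likelihood-ratio tests compare fixed-effects
structures, and REML likelihoods are not comparable across them. Time is
mean-centred within the analysis subset and the centring constant is carried
in the fit. A singular intercept–slope correlation is refit with independent
random effects, but the diagonal fit is adopted only when no likelihood is
lost — otherwise likelihoods would stop being comparable across fits of the
same data (the singular fit is retained and flagged instead).

`compare_time_models()` fits the same outcome under each candidate time
variable on identical rows and reports AICc (with the small-sample
correction, $k$ counting fixed effects *and* variance components so the
value is auditable from `logLik`, `k`, `n`), ΔAICc, and Nakagawa marginal
R² (fixed-effect variance over fixed + mean random-effect + residual
variance, using the observation-averaged random-slope contribution).
Tau PET models default to linear time; cognition models add the quadratic
term and covary for baseline age, sex, and prior test exposures (practice).
`decline_rate_at()` differentiates the fitted quadratic mean curve:
rate$(t) = \beta_1 + 2\beta_2 (t - c)$ with a delta-method (here exact) SE
from the fixed-effects covariance.

## Time to downstream positivity (inverse regression)

For the average time from one biomarker's onset to another biomarker's
positivity, `fit_crossing_regression()` fits OLS of the outcome value on
biomarker time — cluster-robust covariance by participant by default, since
the observations are longitudinal; the classical covariance is available
for fidelity with analyses that ignored clustering. `invert_to_threshold()`
solves $t^\ast = (\mathrm{thr} - \beta_0)/\beta_1$ and propagates the
coefficient covariance through the gradient
$(-1/\beta_1,\; -(\mathrm{thr}-\beta_0)/\beta_1^2)$ to a 95% Wald interval
($\pm 1.96$ SE). Slopes below $10^{-6}$ units/yr are refused as
unidentifiable rather than extrapolated to multi-century crossings.
`crossing_level()` is the same computation on the level scale (e.g. the
amyloid DVR at which p-tau217 positivity occurs on average). Delta-method
coverage is verified by simulation (93–97% at 500 replicates).

## The synthetic cohort generator

Because the motivating cohort data are available only on request, validation
runs on synthetic cohorts with known ground truth (`cohort_config()` /
`simulate_cohort()`). The generator emulates:

- a **non-accumulating subgroup** (50% by default), flat at a sub-threshold
  level (amyloid 1.05 DVR, p-tau217 0.24 pg/mL) with between-person level SD
  and i.i.d. within-person measurement noise (0.035 DVR, 0.05 pg/mL —
  consistent with PET test-retest of a few percent and plasma assay CVs of
  10–20%);
- an **accumulating subgroup** whose latent trajectories follow a chosen
  rate law — constant, linear-in-value (capped), or logistic — anchored so
  the latent value equals the true threshold exactly at the latent onset
  age, with near-threshold rates matched across laws (≈ 0.02 DVR/yr,
  0.035 pg/mL/yr). Trajectories are clamped at a floor well below threshold
  so accumulators rise smoothly through the threshold region;
- **cohort structure** from the motivating study: 172 participants, baseline
  age 63.2 (SD 6.3), roughly biennial visits with jitter, 3–5 visits per
  PET/plasma modality with independent schedules, 5–7 cognitive visits;
- **downstream lags**: p-tau217 onset = amyloid onset + N(4.25, 4²) years
  (untruncated, so p-tau-first orderings occur); entorhinal and inferior
  temporal tau onsets lag amyloid by N(9.7, 2²) and N(13.1, 2²) years,
  truncated at 0;
- **cognition**: the composite declines quadratically in p-tau217-positive
  time with coefficients β₁ = −0.14 z/yr and β₂ = −0.006 z/yr² — chosen so
  the implied decline rates at 5 and 10 years of p-tau positivity are −0.20
  and −0.26 z/yr — plus practice effects (0.08 z per prior exposure),
  person-level random intercepts and age slopes, and noise (0.25 z).

Everything is a deterministic function of the seed. What the generator does
**not** emulate: assay-specific error structure beyond additive noise,
missing-not-at-random dropout, covariate-dependent progression, and
real-world departures from the autonomous rate law $dv/dt = r(v)$. Passing
recovery tests therefore demonstrates internal consistency of the method
under its own assumptions, not accuracy on any particular real cohort.

## Numerical choices and degenerate inputs

- Euler step `dt = 0.05` yr; errors are $O(dt)$ and onset recovery on
  noise-free data is exact to within one step.
- Rate floor $10^{-4}$ units/yr keeps backward integration finite across
  sub-threshold plateaus; each curve limb is additionally capped at 500
  years.
- GBTM: 20 random restarts, convergence at |Δ log-lik| < 10⁻⁶ or 500
  iterations; residual SD floored at 10⁻⁶ so zero-variance data do not
  degenerate; shared residual variance across groups stabilizes small
  groups.
- Exact threshold values are *negative* (strict `>`); a coincidence-window
  boundary |delta| = 2 is coincident (inclusive).
- LRT statistics within 0.01 of zero are clipped to zero (optimizer
  termination error); larger negative values raise a fitting-quality error.
- Zero-variance predictors, empty groups, all-sub-threshold cohorts, and
  sub-minimum bin occupancy raise informative errors rather than silent
  results.

## Problem sizes used in the validation suite

The test suite exercises cohorts of 25–200 participants, 100 replicates for
model-selection recovery, 500 for delta-method coverage, and 2000 for the
null-calibration checks — sizes at which the binomial tolerances quoted in
the tests are meaningful while the whole suite completes in a few minutes.

## A worked run

```{r example, eval = FALSE}
cfg <- list(simulate = list(n_participants = 172,
                            modalities = c("amyloid_dvr", "ptau217_pgml",
                                           "tau_ec_suvr", "tau_itg_suvr")),
            thresholding = list(n_groups = 2),
            seed = 1)
res <- run_pipeline(cfg, out_dir = "pipeline-out", seed = 1)
res$thresholds$amyloid_dvr
res$timing[1:5, ]
res$cognition$comparison
```

Every artefact CSV written by `run_pipeline()` carries a provenance header
(stage, parameters, seed, package version), and identical configuration plus
seed reproduces byte-identical artefacts.
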