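# biomclock

Temporal modelling of longitudinal Alzheimer's disease biomarkers: when does
each biomarker become abnormal in an individual, and which biomarker clock
best predicts downstream brain tau accumulation and cognitive decline?

`biomclock` is aimed at biostatisticians and imaging/fluid-biomarker
researchers working with longitudinal cohorts of amyloid PET (cortical DVR),
plasma p-tau217 (pg/mL), regional tau PET (SUVR), and cognitive composite
scores. It implements, end to end:

- **Data-driven positivity thresholds** via two-step group-based trajectory
  modelling (GBTM): an EM-fitted finite mixture of polynomial trajectories
  identifies a non-accumulating group, and the threshold is that group's
  intercept plus the 95th percentile of its members' within-person SDs —
  a level that stable measurement noise rarely exceeds.
- **SILA** (sampled iterative local approximation): person-level rates
  (OLS slopes of value on age) are binned against value, smoothed, and
  Euler-integrated into a single value-versus-time curve with time zero
  anchored at the positivity threshold, `v(0) = thr`, `dv/dt = r(v)`. Each
  participant's reference observation (first supra-threshold, or last if
  never positive) is aligned to the curve to estimate their **biomarker
  onset age** = reference age − estimated biomarker-positive time.
- **Onset timing** comparisons across biomarkers: deltas, A-first /
  coincident / p-tau-first classification (±2-year window), Pearson
  correlations of onset age with the onset delta, Welch t-tests across sex
  and APOE-ε4.
- **Biomarker-clock model comparison**: linear mixed-effects models (ML) of
  tau PET and cognition under age, amyloid-positive time, or
  p-tau217-positive time, compared by AICc
  (`−2ℓ + 2k + 2k(k+1)/(n−k−1)`), Nakagawa marginal R², and likelihood-ratio
  tests; post hoc decline rates `β₁ + 2β₂(t − c)` with delta-method SEs.
- **Time to downstream positivity** by inverse regression: OLS of an outcome
  biomarker on biomarker time, inverted at the outcome threshold,
  `t* = (thr − β₀)/β₁`, with a delta-method Wald 95% CI.
- A **synthetic cohort generator** with known latent onset ages (constant,
  linear-in-value, and logistic accumulation laws; lagged tau onsets;
  quadratic cognitive decline with practice effects) so every stage is
  validated against ground truth.

## Worked example

```r
library(biomclock)

coh <- simulate_cohort(cohort_config(n_participants = 120, seed = 7))
amy <- coh$data[coh$data$modality == "amyloid_dvr", ]

fit <- gbtm(amy, n_groups = 2, seed = 7)
thr <- derive_threshold(fit, amy, modality = "amyloid_dvr")
thr
#> Positivity threshold (amyloid_dvr): 1.132
#>   = non-accumulator intercept 1.065 + 95% within-person SD 0.06689
#>   n non-accumulators: 72 (quantile type 7)

sf <- sila(amy, thr, modality = "amyloid_dvr")
sf
#> SILA accumulation model (amyloid_dvr)
#>   threshold (time 0): 1.132; Euler dt 0.05 y
#>   curve spans -107.0 to 30.6 years since threshold (values 0.9747-1.648)
#>   rate points: 120 participants; 40 value bins

onsets <- predict(sf, amy)
head(onsets[onsets$observed_positive,
            c("participant_id", "reference_age",
              "positive_time_at_reference", "onset_age")], 4)
#>   participant_id reference_age positive_time_at_reference onset_age
#> 1          P0001      55.43415                   2.699247  52.73490
#> 2          P0002      73.09031                  16.418623  56.67169
#> 3          P0003      67.53723                  15.932420  51.60481
#> 4          P0004      71.50732                   5.443577  66.06375
```

The threshold line reads: stable (non-accumulating) participants sit near
1.065 DVR, and their visit-to-visit scatter implies that only values above
1.132 DVR are distinguishable from measurement noise. The onset table says,
e.g., that participant P0002 was 16.4 years past threshold at their
reference scan (age 73.1), so their amyloid onset age is estimated at 56.7.

Comparing the two plasma/PET clocks on the same cohort:

```r
ptau <- coh$data[coh$data$modality == "ptau217_pgml", ]
thr_p <- derive_threshold(gbtm(ptau, n_groups = 2, seed = 7), ptau,
                          modality = "ptau217_pgml")
rec <- build_timing_records(onsets, predict(sila(ptau, thr_p), ptau),
                            classify_positivity(amy, thr),
                            classify_positivity(ptau, thr_p))
dual <- rec[!is.na(rec$delta_A_to_ptau), ]
mean(dual$delta_A_to_ptau); table(dual$timing_group)
#> [1] 6.28   (SD 5.30 years, n = 45)
#>    A_first coincident ptau_first
#>         37          4          4
```

so amyloid positivity precedes p-tau217 positivity by ~6 years on average in
this synthetic cohort, with a sizeable minority coincident or reversed —
the generator draws the p-tau lag from N(4.25, 4²) and the analysis
recovers that structure through two independently derived thresholds and
curves.

`run_pipeline(config, out_dir)` chains all stages (thresholds → SILA →
onsets → timing → mixed models → crossing times) and writes one CSV per
stage with a provenance header; identical config + seed gives byte-identical
artefacts.

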