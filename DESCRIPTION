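Package: biomclock
Title: Biomarker Clocks for Preclinical Alzheimer's Disease: Thresholds,
    Onset Ages and Timing Analyses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Temporal modelling of longitudinal Alzheimer's disease
    biomarkers (amyloid PET DVR, plasma p-tau217, regional tau PET SUVR)
    and cognition. Derives data-driven positivity thresholds with a
    two-step group-based trajectory modelling (GBTM) procedure, models
    biomarker accumulation with sampled iterative local approximation
    (SILA; discrete rate-versus-value sampling and Euler integration
    anchored at the positivity threshold), estimates person-level
    biomarker onset ages and durations of positivity, compares onset
    timing across biomarkers, compares mixed-effects models of tau PET
    and cognitive decline under competing time operationalizations
    (age, amyloid-positive time, p-tau217-positive time) with AICc and
    marginal R-squared, and estimates average times to downstream
    biomarker positivity by inverse regression with delta-method Wald
    intervals. Includes a synthetic longitudinal cohort generator with
    known latent onset ages for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    lme4,
    sandwich,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
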