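test_that("configuration validation names the offending field", {
  expect_error(cohort_config(frac_accumulators = 1.5), "frac_accumulators")
  expect_error(cohort_config(visits_min = 0), "visits_min")
  expect_error(cohort_config(visit_interval = -1), "visit_interval")
  expect_error(cohort_config(noise_sd = c(amyloid_dvr = -0.1, ptau217_pgml = 0.05,
                                          pacc3_z = 0.25)),
               "noise_sd")
  expect_error(cohort_config(nonacc_level = c(amyloid_dvr = 1.2, ptau217_pgml = 0.2,
                                              tau_ec_suvr = 1.05, tau_itg_suvr = 1.1)),
               "nonacc_level")
})

test_that("a zero-accumulator cohort is flat within noise and has no onsets", {
  cfg <- cohort_config(n_participants = 25, frac_accumulators = 0, seed = 42)
  coh <- simulate_cohort(cfg)
  expect_true(all(coh$truth$group == "non-accumulator"))
  expect_true(all(is.na(coh$truth$onset_amyloid_dvr)))
  expect_true(all(is.na(coh$truth$onset_ptau217_pgml)))
  amy <- coh$data[coh$data$modality == "amyloid_dvr", ]
  spreads <- tapply(amy$value, amy$participant_id, function(v) diff(range(v)))
  expect_lt(max(spreads), 6 * cfg$noise_sd[["amyloid_dvr"]])
})

test_that("identical configurations and seeds give identical cohorts", {
  c1 <- simulate_cohort(cohort_config(n_participants = 40, seed = 9))
  c2 <- simulate_cohort(cohort_config(n_participants = 40, seed = 9))
  expect_identical(c1$data, c2$data)
  expect_identical(c1$truth, c2$truth)
  c3 <- simulate_cohort(cohort_config(n_participants = 40, seed = 10))
  expect_false(identical(c3$data, c1$data))
})

test_that("noise-free constant-rate accumulators follow v(t) = threshold + r t", {
  coh <- simulate_cohort(noise_free_config(n = 30, rate = 0.02))
  tr <- coh$truth
  acc <- tr[tr$group == "accumulator", ]
  for (i in seq_len(nrow(acc))) {
    onset <- acc$onset_amyloid_dvr[i]
    expect_equal(latent_value(coh, acc$participant_id[i], "amyloid_dvr", onset + 5),
                 1.14 + 0.02 * 5, tolerance = 1e-12)
    # latent value at the true onset age equals the true threshold exactly
    expect_equal(latent_value(coh, acc$participant_id[i], "amyloid_dvr", onset),
                 1.14, tolerance = 1e-12)
  }
  # observed values are exactly latent under zero noise
  amy <- coh$data[coh$data$modality == "amyloid_dvr", ]
  one <- amy[amy$participant_id == acc$participant_id[1], ]
  expect_equal(one$value,
               latent_value(coh, acc$participant_id[1], "amyloid_dvr", one$age_years),
               tolerance = 1e-12)
})

test_that("linear-in-value law matches the exponential closed form", {
  cfg <- cohort_config(
    n_participants = 10, frac_accumulators = 1, rate_law = "linear_in_value",
    rate_params = list(amyloid_dvr = list(k = 0.1, cap = 100),
                       ptau217_pgml = list(k = 0.1, cap = 100),
                       tau_ec_suvr = list(k = 0.1, cap = 100),
                       tau_itg_suvr = list(k = 0.1, cap = 100)),
    noise_sd = c(amyloid_dvr = 0, ptau217_pgml = 0, pacc3_z = 0),
    seed = 3)
  coh <- simulate_cohort(cfg)
  p <- coh$truth$participant_id[1]
  onset <- coh$truth$onset_ptau217_pgml[1]
  # dv/dt = k v with v(0) = 0.34 integrates to 0.34 exp(k t)
  expect_equal(latent_value(coh, p, "ptau217_pgml", onset + 10),
               0.34 * exp(1), tolerance = 1e-10)
})

test_that("logistic law matches its closed form and all laws anchor at threshold", {
  for (law in c("constant", "linear_in_value", "logistic")) {
    coh <- simulate_cohort(noise_free_config(n = 16, law = law, seed = 77))
    acc <- coh$truth[coh$truth$group == "accumulator", ]
    vals <- vapply(seq_len(nrow(acc)), function(i)
      latent_value(coh, acc$participant_id[i], "amyloid_dvr",
                   acc$onset_amyloid_dvr[i]), numeric(1))
    expect_equal(vals, rep(1.14, nrow(acc)), tolerance = 1e-10)
  }
  # logistic closed form: v(t) = vmax / (1 + a exp(-k t))
  cfg <- noise_free_config(n = 6, law = "logistic", seed = 5)
  coh <- simulate_cohort(cfg)
  p <- coh$truth$participant_id[1]
  onset <- coh$truth$onset_amyloid_dvr[1]
  pars <- cfg$rate_params$amyloid_dvr
  a <- (pars$vmax - 1.14) / 1.14
  expect_equal(latent_value(coh, p, "amyloid_dvr", onset + 7),
               pars$vmax / (1 + a * exp(-pars$k * 7)), tolerance = 1e-10)
})

test_that("latent_value rejects out-of-domain ages and unknown participants", {
  coh <- simulate_cohort(cohort_config(n_participants = 5, seed = 1))
  expect_error(latent_value(coh, "P0001", "amyloid_dvr", -5), "domain")
  expect_error(latent_value(coh, "nobody", "amyloid_dvr", 60), "participant")
})

test_that("cohort CSV round-trips losslessly", {
  # header-only file reads back empty
  empty <- structure(list(data = data.frame(participant_id = character(),
                                            modality = character(),
                                            age_years = numeric(),
                                            value = numeric()),
                          truth = NULL, config = NULL), class = "cohort")
  d1 <- withr::local_tempdir()
  write_cohort(empty, d1)
  back <- read_cohort(d1)
  expect_equal(nrow(back$data), 0)

  # hand-written 3-row table: one participant, one modality, three visits
  d2 <- withr::local_tempdir()
  writeLines(c("participant_id,modality,age_years,value",
               "A,amyloid_dvr,60,1.0", "A,amyloid_dvr,62,1.1",
               "A,amyloid_dvr,64,1.2"),
             file.path(d2, "observations.csv"))
  back2 <- read_cohort(d2)
  expect_equal(unique(back2$data$participant_id), "A")
  expect_equal(nrow(back2$data), 3)

  # simulated cohort round-trips to within float round-trip
  coh <- simulate_cohort(cohort_config(n_participants = 50, seed = 21))
  d3 <- withr::local_tempdir()
  write_cohort(coh, d3)
  back3 <- read_cohort(d3)
  expect_equal(back3$data$value, coh$data$value, tolerance = 1e-12)
  expect_equal(back3$data$age_years, coh$data$age_years, tolerance = 1e-12)
  expect_identical(back3$data$participant_id, coh$data$participant_id)
  expect_equal(back3$truth$onset_amyloid_dvr, coh$truth$onset_amyloid_dvr,
               tolerance = 1e-12)
})

test_that("malformed rows raise a parse error with a line number", {
  d <- withr::local_tempdir()
  writeLines(c("participant_id,modality,age_years,value",
               "A,amyloid_dvr,60,1.0", "A,amyloid_dvr,62,oops"),
             file.path(d, "observations.csv"))
  expect_error(read_cohort(d), "line 3")
})

test_that("within-person scatter converges to the configured noise SD", {
  cfg <- cohort_config(n_participants = 30, frac_accumulators = 0,
                       visits_min = 100, visits_max = 100,
                       visit_interval = 0.3, visit_jitter_sd = 0.01,
                       pacc_visits_min = 1, pacc_visits_max = 1,
                       seed = 6)
  coh <- simulate_cohort(cfg)
  amy <- coh$data[coh$data$modality == "amyloid_dvr", ]
  sds <- within_person_sd(amy)
  expect_equal(mean(sds), cfg$noise_sd[["amyloid_dvr"]], tolerance = 0.1)
})
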