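test_that("per-participant rates are OLS slopes with mean mid-values", {
  d <- long_series("a", c(60, 62), c(1.00, 1.10))
  r <- estimate_rates(d)
  expect_equal(r$rate, 0.05, tolerance = 1e-12)
  expect_equal(r$mid_value, 1.05, tolerance = 1e-12)
  flat <- long_series("b", c(60, 62, 64), c(1.2, 1.2, 1.2))
  expect_equal(estimate_rates(flat)$rate, 0, tolerance = 1e-12)
  # single-visit participants contribute no rate point
  expect_error(estimate_rates(long_series("c", 60, 1)), "cannot model")
})

test_that("noise-free constant-law accumulators all have the generative rate", {
  coh <- simulate_cohort(noise_free_config(n = 40, rate = 0.02))
  amy <- coh$data[coh$data$modality == "amyloid_dvr", ]
  r <- estimate_rates(amy)
  acc <- coh$truth$participant_id[coh$truth$group == "accumulator"]
  expect_equal(r$rate[r$participant_id %in% acc],
               rep(0.02, sum(r$participant_id %in% acc)), tolerance = 1e-9)
})

test_that("rate binning reproduces flat and proportional laws", {
  pts <- data.frame(participant_id = as.character(1:200),
                    mid_value = seq(0.2, 1.0, length.out = 200),
                    rate = 0.02, n_obs = 3)
  s <- sample_rate_curve(pts, n_bins = 20, smooth_window = 1)
  expect_equal(s$mean_rate, rep(0.02, 20), tolerance = 1e-12)

  pts2 <- transform(pts, rate = 0.1 * mid_value)
  s2 <- sample_rate_curve(pts2, n_bins = 20, smooth_window = 1)
  expect_true(all(abs(s2$mean_rate - 0.1 * s2$bin_center) <
                    0.05 * 0.1 * s2$bin_center))
})

test_that("sparse bins are filled by interpolating occupied neighbours", {
  # 3 bins over [0, 3): dense at 0.5 and 2.5, single point at 1.5
  pts <- data.frame(participant_id = as.character(1:9),
                    mid_value = c(rep(0.5, 4), 1.5, rep(2.5, 4)),
                    rate = c(rep(0.01, 4), 99, rep(0.03, 4)), n_obs = 3)
  s <- sample_rate_curve(pts, n_bins = 3, min_per_bin = 3, smooth_window = 1,
                         value_range = c(0, 3))
  expect_true(s$interpolated[2])
  expect_equal(s$mean_rate[2], mean(c(0.01, 0.03)), tolerance = 1e-12)
  expect_error(sample_rate_curve(pts, n_bins = 3, min_per_bin = 10),
               "minimum")
})

test_that("Euler integration is exact under a constant rate", {
  curve <- constant_curve(threshold = 1.14, r = 0.02, dt = 0.1)
  v10 <- curve$value[which.min(abs(curve$time - 10))]
  expect_equal(v10, 1.34, tolerance = 1e-10)
  # anchor: value at time zero is the threshold
  expect_equal(curve$value[curve$time == 0], 1.14, tolerance = 1e-12)
  # uniform grid, strictly increasing values
  expect_equal(diff(range(diff(curve$time))), 0, tolerance = 1e-9)
  expect_true(all(diff(curve$value) > 0))
})

test_that("Euler integration converges first-order to the exponential solution", {
  samples <- data.frame(bin_center = seq(0.05, 1.2, by = 0.001))
  samples$mean_rate <- 0.1 * samples$bin_center
  err_at <- function(dt) {
    cv <- integrate_curve(samples, 0.34, dt = dt, domain = c(0.05, 1.2))
    v10 <- approx(cv$time, cv$value, xout = 10)$y
    abs(v10 - 0.34 * exp(1))
  }
  e1 <- err_at(0.01)
  expect_lt(e1, 0.005)
  # halving the step roughly halves the error
  e2 <- err_at(0.005)
  expect_gt(e1 / e2, 1.6)
  expect_lt(e1 / e2, 2.4)
})

test_that("curve inversion is exact on the curve and flags extrapolation", {
  curve <- constant_curve(threshold = 1.14, r = 0.02)
  expect_equal(as.numeric(invert_curve(curve, 1.34)), 10, tolerance = 1e-9)
  expect_equal(as.numeric(invert_curve(curve, 1.14)), 0, tolerance = 1e-12)
  # round trip at random times
  set.seed(2)
  ts <- runif(50, min(curve$time), max(curve$time))
  vs <- curve_value_at(curve, ts)
  back <- as.numeric(invert_curve(curve, vs))
  expect_lt(max(abs(back - ts)), attr(curve, "dt"))
  # extrapolation beyond the modelled range extends the terminal slope
  top <- max(curve$value)
  t_top <- max(curve$time)
  ext <- invert_curve(curve, top + 0.02)
  expect_true(attr(ext, "extrapolated"))
  expect_equal(as.numeric(ext), t_top + 0.02 / 0.02, tolerance = 1e-6)
  expect_error(invert_curve(curve, top + 0.02, extrapolate = FALSE), "range")
})

test_that("the reference observation follows the first-positive / last rule", {
  s <- long_series("a", c(60, 62, 64), c(0.30, 0.36, 0.40))
  ref <- select_reference_observation(s, 0.34)
  expect_equal(ref$age, 62)
  expect_true(ref$observed_positive)
  s2 <- long_series("b", c(60, 62, 64), c(0.30, 0.31, 0.33))
  ref2 <- select_reference_observation(s2, 0.34)
  expect_equal(ref2$age, 64)
  expect_false(ref2$observed_positive)
  s3 <- long_series("c", c(60, 62), c(0.40, 0.45))
  expect_equal(select_reference_observation(s3, 0.34)$age, 60)
})

test_that("onset age is the reference age minus the positive time", {
  curve <- constant_curve(threshold = 1.14, r = 0.02)
  fit <- structure(list(curve = curve, threshold = 1.14, modality = "amyloid_dvr"),
                   class = "sila")
  d <- long_series("obs_pos", 70, 1.34)
  on <- estimate_onset(fit, d)
  expect_equal(on$positive_time_at_reference, 10, tolerance = 1e-9)
  expect_equal(on$onset_age, 60, tolerance = 1e-9)
  # onset-age identity
  expect_equal(on$onset_age,
               on$reference_age - on$positive_time_at_reference,
               tolerance = 1e-9)
  # sub-threshold reference projects a future onset via the backward limb
  d2 <- long_series("still_neg", 70, 1.04)
  on2 <- estimate_onset(fit, d2)
  expect_equal(on2$positive_time_at_reference, -5, tolerance = 1e-6)
  expect_equal(on2$onset_age, 75, tolerance = 1e-6)
  expect_false(on2$observed_positive)
})

test_that("ordering is preserved: higher value at the same age, earlier onset", {
  curve <- constant_curve()
  fit <- structure(list(curve = curve, threshold = 1.14, modality = "amyloid_dvr"),
                   class = "sila")
  d <- rbind(long_series("low", 70, 1.20), long_series("high", 70, 1.40))
  on <- estimate_onset(fit, d)
  expect_lt(on$onset_age[on$participant_id == "high"],
            on$onset_age[on$participant_id == "low"])
})

test_that("noise-free cohorts recover true onset ages within integration error", {
  coh <- simulate_cohort(noise_free_config(n = 80, rate = 0.02, seed = 19))
  amy <- coh$data[coh$data$modality == "amyloid_dvr", ]
  fit <- sila(amy, 1.14, modality = "amyloid_dvr")
  on <- predict(fit, amy)
  tr <- coh$truth
  ids <- intersect(tr$participant_id[tr$group == "accumulator"],
                   on$participant_id[on$observed_positive])
  expect_gt(length(ids), 20)
  err <- on$onset_age[match(ids, on$participant_id)] -
    tr$onset_amyloid_dvr[match(ids, tr$participant_id)]
  expect_lt(max(abs(err)), 2 * fit$params$dt)
})

test_that("round-trip self-consistency holds for observations on the curve", {
  curve <- constant_curve()
  fit <- structure(list(curve = curve, threshold = 1.14, modality = "amyloid_dvr"),
                   class = "sila")
  set.seed(7)
  onset_true <- runif(30, 55, 70)
  d <- do.call(rbind, lapply(seq_along(onset_true), function(i) {
    ages <- onset_true[i] + sort(runif(3, 0.5, 12))
    long_series(sprintf("q%02d", i), ages,
                curve_value_at(curve, ages - onset_true[i]))
  }))
  on <- estimate_onset(fit, d)
  err <- on$onset_age[match(sprintf("q%02d", seq_along(onset_true)),
                            on$participant_id)] - onset_true
  expect_lt(max(abs(err)), attr(curve, "dt"))
})

test_that("modelled values at given ages sit on the curve", {
  curve <- constant_curve()
  fit <- structure(list(curve = curve, threshold = 1.14, modality = "amyloid_dvr"),
                   class = "sila")
  onsets <- data.frame(participant_id = "a", onset_age = 60)
  v <- estimate_value_at(fit, onsets, c(a = 65))
  expect_equal(v$value, 1.24, tolerance = 1e-9)
  v0 <- estimate_value_at(fit, onsets, c(a = 60))
  expect_equal(v0$value, 1.14, tolerance = 1e-12)
})

test_that("concentration RMSE is zero on the curve and tracks the noise SD", {
  curve <- constant_curve()
  fit <- structure(list(curve = curve, threshold = 1.14, modality = "amyloid_dvr"),
                   class = "sila")
  d <- long_series("a", 65, curve_value_at(curve, 5))
  onsets <- data.frame(participant_id = "a", onset_age = 60)
  expect_equal(concentration_rmse(fit, d, onsets), 0, tolerance = 1e-9)

  set.seed(12)
  n <- 1000
  ids <- sprintf("r%03d", seq_len(n))
  onsets2 <- data.frame(participant_id = ids, onset_age = runif(n, 55, 65))
  ages <- onsets2$onset_age + runif(n, 0, 15)
  sigma <- 0.05
  d2 <- data.frame(participant_id = ids, modality = "amyloid_dvr",
                   age_years = ages,
                   value = curve_value_at(curve, ages - onsets2$onset_age) +
                     rnorm(n, 0, sigma))
  expect_equal(concentration_rmse(fit, d2, onsets2), sigma, tolerance = 0.1)
})

test_that("converter validation measures onset vs crossing midpoint", {
  # single converter: last-negative at 64, first-positive at 66, onset 64.5
  d <- long_series("c1", c(62, 64, 66), c(1.05, 1.10, 1.20))
  onsets <- data.frame(participant_id = "c1", onset_age = 64.5)
  v <- validate_converters(d, onsets, 1.14)
  expect_equal(v$n, 1L)
  expect_equal(v$mean_difference, -0.5, tolerance = 1e-12)

  # onsets exactly at midpoints: mean 0 and CI contains 0
  d2 <- rbind(d, long_series("c2", c(60, 63), c(1.0, 1.3)))
  onsets2 <- data.frame(participant_id = c("c1", "c2"),
                        onset_age = c(65, 61.5))
  v2 <- validate_converters(d2, onsets2, 1.14)
  expect_equal(v2$mean_difference, 0, tolerance = 1e-12)
  expect_true(v2$ci[1] <= 0 && v2$ci[2] >= 0)

  # no converters: empty result with a notice
  d3 <- long_series("neg", c(60, 62), c(1.0, 1.05))
  expect_message(v3 <- validate_converters(d3, onsets, 1.14), "no observed")
  expect_equal(v3$n, 0L)
})
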