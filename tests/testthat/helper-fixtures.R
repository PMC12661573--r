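# Shared fixtures, built in code at test time.

# small noise-free cohort under the constant law with early onsets, so every
# accumulator's observation window lies entirely in the rising regime
noise_free_config <- function(n = 60, seed = 101, rate = 0.02, law = "constant") {
  cohort_config(
    n_participants = n, frac_accumulators = 0.5,
    noise_sd = c(amyloid_dvr = 0, ptau217_pgml = 0, tau_ec_suvr = 0,
                 tau_itg_suvr = 0, pacc3_z = 0),
    nonacc_level_sd = c(amyloid_dvr = 0, ptau217_pgml = 0, tau_ec_suvr = 0,
                        tau_itg_suvr = 0),
    rate_law = law,
    rate_params = if (law == "constant")
      list(amyloid_dvr = list(r = rate), ptau217_pgml = list(r = 0.035),
           tau_ec_suvr = list(r = 0.04), tau_itg_suvr = list(r = 0.045))
    else NULL,
    value_floor = c(amyloid_dvr = 0.5, ptau217_pgml = 0.05,
                    tau_ec_suvr = 0.6, tau_itg_suvr = 0.6),
    onset_age_mean = 62, onset_age_sd = 4,
    baseline_age_mean = 64, baseline_age_sd = 3,
    modalities = c("amyloid_dvr", "ptau217_pgml"),
    seed = seed)
}

# long table for hand-built series
long_series <- function(id, ages, values, modality = "amyloid_dvr") {
  data.frame(participant_id = id, modality = modality,
             age_years = ages, value = values, stringsAsFactors = FALSE)
}

# two clearly separated trajectory groups for GBTM tests: flat vs rising
two_group_data <- function(n_per_group = 50, n_visits = 4, noise = 0.02,
                           flat_level = 1.0, slope = 0.03, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(2 * n_per_group)) {
    ages <- 60 + seq(0, by = 2, length.out = n_visits) + stats::runif(1, 0, 1)
    rising <- i > n_per_group
    mu <- if (rising) 1.05 + slope * (ages - 60) else flat_level
    rows[[i]] <- long_series(sprintf("S%03d", i), ages,
                             mu + stats::rnorm(n_visits, 0, noise))
  }
  list(data = do.call(rbind, rows),
       truth = rep(c("flat", "rising"), each = n_per_group))
}

# exact SILA curve for the constant law: v(t) = threshold + r t
constant_curve <- function(threshold = 1.14, r = 0.02, dt = 0.05,
                           span = c(-10, 25)) {
  samples <- data.frame(bin_center = seq(threshold + r * span[1] - 0.1,
                                         threshold + r * span[2] + 0.1,
                                         length.out = 50),
                        mean_rate = r)
  integrate_curve(samples, threshold, dt = dt,
                  domain = range(samples$bin_center))
}
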