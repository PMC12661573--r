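#' Configure a synthetic longitudinal biomarker cohort
#'
#' Builds a validated configuration for [simulate_cohort()]. The generator
#' emulates a preclinical Alzheimer's disease observational cohort: a
#' non-accumulating subgroup with stable sub-threshold biomarker levels plus
#' within-person measurement noise, and an accumulating subgroup whose latent
#' trajectories follow a monotone rate-versus-value law \eqn{dv/dt = r(v)}
#' that crosses the positivity threshold exactly at a latent onset age.
#' Plasma p-tau217 onset lags amyloid onset (lag may be negative); regional
#' tau PET onsets lag amyloid onset with lags truncated at zero; the
#' cognitive composite declines as a quadratic function of p-tau217-positive
#' time with practice effects.
#'
#' @param n_participants number of participants.
#' @param frac_accumulators proportion of participants in the accumulating
#'   subgroup, in \[0, 1\].
#' @param visit_interval mean inter-visit interval in years.
#' @param visit_jitter_sd SD of the Gaussian jitter added to each interval
#'   (intervals are floored at 0.25 years).
#' @param visits_min,visits_max per-modality visit count range (inclusive);
#'   counts are drawn uniformly per participant and modality.
#' @param pacc_visits_min,pacc_visits_max visit count range for the cognitive
#'   composite (typically denser than PET/plasma schedules).
#' @param baseline_age_mean,baseline_age_sd baseline age distribution (years).
#' @param rate_law accumulation law: `"constant"` (\eqn{r(v) = r}),
#'   `"linear_in_value"` (\eqn{r(v) = k\,\min(v, cap)}), or `"logistic"`
#'   (\eqn{r(v) = k\,v\,(1 - v/v_{max})}).
#' @param rate_params named list of per-modality parameter lists for the
#'   chosen law; `NULL` uses modality defaults (see Details).
#' @param noise_sd named vector of within-person measurement SDs per modality.
#' @param thresholds_true named vector of latent positivity thresholds.
#' @param nonacc_level named vector of mean stable levels for
#'   non-accumulators (must lie below the thresholds).
#' @param nonacc_level_sd named vector of between-person SDs of the stable
#'   level.
#' @param onset_age_mean,onset_age_sd amyloid onset age distribution for
#'   accumulators (years).
#' @param ptau_lag_mean,ptau_lag_sd Gaussian lag from amyloid onset to
#'   p-tau217 onset (years; not truncated, so p-tau-first orderings occur).
#' @param tau_lag named vector of mean lags (years) from amyloid onset to
#'   entorhinal (`tau_ec_suvr`) and inferior temporal (`tau_itg_suvr`) tau
#'   onset; Gaussian with SD `tau_lag_sd`, truncated at 0.
#' @param tau_lag_sd SD of the tau onset lags.
#' @param cognition_params list with elements `b0` (baseline composite),
#'   `beta_lin`, `beta_quad` (decline in z/year and z/year^2 as a function of
#'   p-tau217-positive time), `practice` (gain per prior test exposure),
#'   `ri_sd`, `rs_sd` (random intercept / age-slope SDs).
#' @param value_floor named vector: accumulator latent trajectories are
#'   clamped at this floor when run backwards below threshold. Defaults sit
#'   well below the thresholds so accumulators rise smoothly through the
#'   threshold region rather than jumping off a plateau (`NULL` falls back
#'   to `nonacc_level`).
#' @param modalities accumulation modalities to simulate; cognition
#'   (`pacc3_z`) is always generated.
#' @param seed integer seed; the whole cohort is a deterministic function of
#'   the configuration.
#'
#' @details Default rate parameters are chosen to mirror observed magnitudes
#' of biomarker change: amyloid DVR ~0.02/yr, plasma p-tau217 ~0.035 pg/mL/yr,
#' entorhinal / inferior temporal tau SUVR 0.040 / 0.045 /yr under the
#' constant law; `linear_in_value` uses k = 0.10/yr capped at 4x threshold and
#' `logistic` k = 0.25/yr with carrying capacity 3x threshold.
#'
#' @return an object of class `cohort_config` (a validated list).
#' @seealso [simulate_cohort()]
#' @export
cohort_config <- function(n_participants = 172,
                          frac_accumulators = 0.5,
                          visit_interval = 2,
                          visit_jitter_sd = 0.3,
                          visits_min = 3,
                          visits_max = 5,
                          pacc_visits_min = 5,
                          pacc_visits_max = 7,
                          baseline_age_mean = 63.2,
                          baseline_age_sd = 6.3,
                          rate_law = c("constant", "linear_in_value", "logistic"),
                          rate_params = NULL,
                          noise_sd = c(amyloid_dvr = 0.035, ptau217_pgml = 0.05,
                                       tau_ec_suvr = 0.04, tau_itg_suvr = 0.04,
                                       pacc3_z = 0.25),
                          thresholds_true = c(amyloid_dvr = 1.14,
                                              ptau217_pgml = 0.34,
                                              tau_ec_suvr = 1.27,
                                              tau_itg_suvr = 1.42),
                          nonacc_level = c(amyloid_dvr = 1.05,
                                           ptau217_pgml = 0.24,
                                           tau_ec_suvr = 1.08,
                                           tau_itg_suvr = 1.12),
                          nonacc_level_sd = c(amyloid_dvr = 0.02,
                                              ptau217_pgml = 0.02,
                                              tau_ec_suvr = 0.03,
                                              tau_itg_suvr = 0.03),
                          onset_age_mean = 58,
                          onset_age_sd = 7,
                          ptau_lag_mean = 4.25,
                          ptau_lag_sd = 4,
                          tau_lag = c(tau_ec_suvr = 9.7, tau_itg_suvr = 13.1),
                          tau_lag_sd = 2,
                          cognition_params = list(b0 = 0.1,
                                                  beta_lin = -0.14,
                                                  beta_quad = -0.006,
                                                  practice = 0.08,
                                                  ri_sd = 0.40,
                                                  rs_sd = 0.015),
                          value_floor = c(amyloid_dvr = 1.00,
                                          ptau217_pgml = 0.20,
                                          tau_ec_suvr = 1.03,
                                          tau_itg_suvr = 1.07),
                          modalities = c("amyloid_dvr", "ptau217_pgml"),
                          seed = 1L) {
  rate_law <- match.arg(rate_law)
  cfg <- list(n_participants = n_participants,
              frac_accumulators = frac_accumulators,
              visit_interval = visit_interval,
              visit_jitter_sd = visit_jitter_sd,
              visits_min = visits_min, visits_max = visits_max,
              pacc_visits_min = pacc_visits_min, pacc_visits_max = pacc_visits_max,
              baseline_age_mean = baseline_age_mean,
              baseline_age_sd = baseline_age_sd,
              rate_law = rate_law,
              rate_params = rate_params,
              noise_sd = noise_sd,
              thresholds_true = thresholds_true,
              nonacc_level = nonacc_level,
              nonacc_level_sd = nonacc_level_sd,
              onset_age_mean = onset_age_mean, onset_age_sd = onset_age_sd,
              ptau_lag_mean = ptau_lag_mean, ptau_lag_sd = ptau_lag_sd,
              tau_lag = tau_lag, tau_lag_sd = tau_lag_sd,
              cognition_params = cognition_params,
              value_floor = value_floor,
              modalities = modalities,
              seed = as.integer(seed))
  if (is.null(cfg$rate_params)) cfg$rate_params <- default_rate_params(cfg)
  if (is.null(cfg$value_floor)) cfg$value_floor <- cfg$nonacc_level
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

default_rate_params <- function(cfg) {
  thr <- cfg$thresholds_true
  # near-threshold accumulation rates matched across laws (units/year)
  r0 <- c(amyloid_dvr = 0.02, ptau217_pgml = 0.035,
          tau_ec_suvr = 0.040, tau_itg_suvr = 0.045)
  mk <- function(m) {
    switch(cfg$rate_law,
           constant = list(r = r0[[m]]),
           linear_in_value = list(k = r0[[m]] / thr[[m]], cap = 2.5 * thr[[m]]),
           logistic = {
             vmax <- 2.2 * thr[[m]]
             list(k = r0[[m]] / (thr[[m]] * (1 - thr[[m]] / vmax)),
                  vmax = vmax)
           })
  }
  p <- lapply(names(thr), mk)
  names(p) <- names(thr)
  p
}

cfg_fail <- function(field, msg) {
  stop(sprintf("invalid cohort configuration: field '%s' %s", field, msg),
       call. = FALSE)
}

validate_cohort_config <- function(cfg) {
  if (!is.numeric(cfg$n_participants) || cfg$n_participants < 1)
    cfg_fail("n_participants", "must be >= 1")
  if (cfg$frac_accumulators < 0 || cfg$frac_accumulators > 1)
    cfg_fail("frac_accumulators", "must lie in [0, 1]")
  for (f in c("visit_jitter_sd", "baseline_age_sd", "onset_age_sd",
              "ptau_lag_sd", "tau_lag_sd"))
    if (cfg[[f]] < 0) cfg_fail(f, "must be >= 0")
  if (any(cfg$noise_sd < 0)) cfg_fail("noise_sd", "must be >= 0")
  if (any(cfg$nonacc_level_sd < 0)) cfg_fail("nonacc_level_sd", "must be >= 0")
  if (cfg$visits_min < 1 || cfg$visits_max < cfg$visits_min)
    cfg_fail("visits_min", "requires 1 <= visits_min <= visits_max")
  if (cfg$pacc_visits_min < 1 || cfg$pacc_visits_max < cfg$pacc_visits_min)
    cfg_fail("pacc_visits_min", "requires 1 <= pacc_visits_min <= pacc_visits_max")
  if (cfg$visit_interval <= 0) cfg_fail("visit_interval", "must be > 0")
  mods <- setdiff(union(cfg$modalities, names(cfg$tau_lag)), "pacc3_z")
  missing_thr <- setdiff(mods, names(cfg$thresholds_true))
  if (length(missing_thr))
    cfg_fail("thresholds_true", paste("missing modality", missing_thr[1]))
  if (any(cfg$nonacc_level[mods] >= cfg$thresholds_true[mods]))
    cfg_fail("nonacc_level", "must lie strictly below thresholds_true")
  # the accumulation rate must be strictly positive above the floor value
  for (m in mods) {
    floorv <- if (is.null(cfg$value_floor)) cfg$nonacc_level[[m]] else cfg$value_floor[[m]]
    r <- rate_law_fun(cfg$rate_law, cfg$rate_params[[m]])(floorv)
    if (!is.finite(r) || r <= 0)
      cfg_fail("rate_params", sprintf("yields non-positive rate at floor for '%s'", m))
  }
  invisible(cfg)
}

# closed-form latent trajectory v(t) with v(0) = threshold, t in years since
# onset; vectorised over t
latent_trajectory_fun <- function(law, params, threshold, floor_value) {
  f <- switch(law,
    constant = function(t) threshold + params$r * t,
    linear_in_value = function(t) {
      cap <- params$cap
      v <- threshold * exp(params$k * t)
      # above the cap the rate is constant at k*cap
      t_cap <- log(cap / threshold) / params$k
      over <- t > t_cap
      v[over] <- cap + params$k * cap * (t[over] - t_cap)
      v
    },
    logistic = function(t) {
      vmax <- params$vmax
      a <- (vmax - threshold) / threshold
      vmax / (1 + a * exp(-params$k * t))
    })
  function(t) pmax(f(t), floor_value)
}

rate_law_fun <- function(law, params) {
  switch(law,
         constant = function(v) rep_len(params$r, length(v)),
         linear_in_value = function(v) params$k * pmin(v, params$cap),
         logistic = function(v) params$k * v * (1 - v / params$vmax))
}

#' Noise-free latent trajectory value for a simulated participant
#'
#' Evaluates the latent (measurement-error-free) biomarker trajectory of a
#' participant from a simulated cohort at arbitrary ages. Non-accumulators
#' return their constant stable level; accumulators return the closed-form
#' solution of the configured rate law, anchored so that the value at the
#' true onset age equals the true threshold exactly.
#'
#' @param cohort a `cohort` object from [simulate_cohort()].
#' @param participant_id a participant identifier present in the cohort.
#' @param modality one of the accumulation modalities in the configuration.
#' @param age vector of ages in years.
#' @return numeric vector of latent values.
#' @export
latent_value <- function(cohort, participant_id, modality, age) {
  stopifnot(inherits(cohort, "cohort"))
  if (!is.numeric(age) || any(!is.finite(age)) || any(age < 0) || any(age > 120))
    stop("age outside supported domain [0, 120]", call. = FALSE)
  tr <- cohort$truth
  row <- tr[tr$participant_id == participant_id, , drop = FALSE]
  if (nrow(row) != 1L)
    stop("unknown participant_id: ", participant_id, call. = FALSE)
  cfg <- cohort$config
  if (!modality %in% names(cfg$thresholds_true))
    stop("unknown modality: ", modality, call. = FALSE)
  onset <- row[[paste0("onset_", modality)]]
  if (row$group == "non-accumulator" || is.na(onset))
    return(rep_len(row[[paste0("level_", modality)]], length(age)))
  f <- latent_trajectory_fun(cfg$rate_law, cfg$rate_params[[modality]],
                             cfg$thresholds_true[[modality]],
                             cfg$value_floor[[modality]])
  f(age - onset)
}

visit_ages <- function(n, baseline, interval, jitter_sd) {
  gaps <- pmax(0.25, stats::rnorm(n - 1, interval, jitter_sd))
  baseline + c(0, cumsum(gaps))
}

#' Simulate a longitudinal multimodal biomarker cohort with known truth
#'
#' Generates long-format longitudinal observations for amyloid PET, plasma
#' p-tau217 (and optionally regional tau PET) plus a cognitive composite,
#' together with the latent ground truth (group labels, true onset ages,
#' stable levels, covariates). Accumulating participants follow the
#' configured rate law exactly (observed value = latent value + i.i.d.
#' Gaussian noise); non-accumulators are flat at a sub-threshold level.
#' Tau PET onsets lag amyloid onset; the cognitive composite declines
#' quadratically in p-tau217-positive time with practice effects and
#' person-level random intercepts and age slopes.
#'
#' @param config a [cohort_config()] object.
#' @return an object of class `cohort`: a list with elements
#'   \describe{
#'     \item{data}{long-format data frame `participant_id, modality,
#'       age_years, value` with ages strictly increasing within participant
#'       and modality}
#'     \item{truth}{one row per participant: `group`, per-modality true onset
#'       ages (`onset_<modality>`, `NA` for non-accumulators), stable levels,
#'       covariates `sex`, `apoe4`, and cognitive random effects}
#'     \item{config}{the configuration used}
#'   }
#' @examples
#' coh <- simulate_cohort(cohort_config(n_participants = 20, seed = 7))
#' head(coh$data)
#' table(coh$truth$group)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_participants
  ids <- sprintf("P%04d", seq_len(n))
  n_acc <- round(cfg$frac_accumulators * n)
  group <- rep(c("accumulator", "non-accumulator"), c(n_acc, n - n_acc))

  mods <- cfg$modalities
  tau_mods <- intersect(names(cfg$tau_lag), mods)

  truth <- data.frame(participant_id = ids, group = group,
                      stringsAsFactors = FALSE)
  truth$sex <- ifelse(stats::runif(n) < 0.65, "female", "male")
  truth$apoe4 <- as.integer(stats::runif(n) < 0.48)
  baseline_age <- stats::rnorm(n, cfg$baseline_age_mean, cfg$baseline_age_sd)
  truth$baseline_age <- baseline_age

  # latent onset ages: amyloid first, p-tau lagged (untruncated), tau lagged
  # (truncated at 0)
  amy_onset <- ifelse(group == "accumulator",
                      stats::rnorm(n, cfg$onset_age_mean, cfg$onset_age_sd), NA_real_)
  ptau_lag <- stats::rnorm(n, cfg$ptau_lag_mean, cfg$ptau_lag_sd)
  onsets <- list(amyloid_dvr = amy_onset,
                 ptau217_pgml = amy_onset + ptau_lag)
  for (m in tau_mods)
    onsets[[m]] <- amy_onset + pmax(0, stats::rnorm(n, cfg$tau_lag[[m]], cfg$tau_lag_sd))
  for (m in names(cfg$thresholds_true))
    truth[[paste0("onset_", m)]] <- if (m %in% names(onsets)) onsets[[m]] else NA_real_
  for (m in names(cfg$thresholds_true))
    truth[[paste0("level_", m)]] <-
      stats::rnorm(n, cfg$nonacc_level[[m]], cfg$nonacc_level_sd[[m]])

  cg <- cfg$cognition_params
  truth$cog_ri <- stats::rnorm(n, 0, cg$ri_sd)
  truth$cog_rs <- stats::rnorm(n, 0, cg$rs_sd)

  rows <- vector("list", n * (length(mods) + 1L))
  k <- 0L
  cohort_stub <- structure(list(truth = truth, config = cfg), class = "cohort")
  for (i in seq_len(n)) {
    for (m in mods) {
      nv <- sample(cfg$visits_min:cfg$visits_max, 1L)
      ages <- visit_ages(nv, baseline_age[i], cfg$visit_interval, cfg$visit_jitter_sd)
      lat <- latent_value(cohort_stub, ids[i], m, ages)
      val <- lat + stats::rnorm(nv, 0, cfg$noise_sd[[m]])
      k <- k + 1L
      rows[[k]] <- data.frame(participant_id = ids[i], modality = m,
                              age_years = ages, value = val,
                              stringsAsFactors = FALSE)
    }
    # cognitive composite: quadratic in p-tau217-positive time + practice
    nv <- sample(cfg$pacc_visits_min:cfg$pacc_visits_max, 1L)
    ages <- visit_ages(nv, baseline_age[i] - 3, cfg$visit_interval, cfg$visit_jitter_sd)
    t_ptau <- if (group[i] == "accumulator") ages - onsets$ptau217_pgml[i] else rep(0, nv)
    mu <- cg$b0 + truth$cog_ri[i] + truth$cog_rs[i] * (ages - baseline_age[i]) +
      cg$practice * (seq_len(nv) - 1L) +
      cg$beta_lin * t_ptau + cg$beta_quad * t_ptau^2
    k <- k + 1L
    rows[[k]] <- data.frame(participant_id = ids[i], modality = "pacc3_z",
                            age_years = ages,
                            value = mu + stats::rnorm(nv, 0, cfg$noise_sd[["pacc3_z"]]),
                            stringsAsFactors = FALSE)
  }
  dat <- do.call(rbind, rows[seq_len(k)])
  rownames(dat) <- NULL
  truth$practice_exposures <- NA_integer_
  pv <- table(dat$participant_id[dat$modality == "pacc3_z"])
  truth$practice_exposures <- as.integer(pv[truth$participant_id])
  structure(list(data = dat, truth = truth, config = cfg), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("Synthetic biomarker cohort\n")
  cat(sprintf("  participants: %d (%d accumulators)\n",
              nrow(x$truth), sum(x$truth$group == "accumulator")))
  cat(sprintf("  observations: %d across %s\n", nrow(x$data),
              paste(unique(x$data$modality), collapse = ", ")))
  cat(sprintf("  rate law: %s; seed: %d\n", x$config$rate_law, x$config$seed))
  invisible(x)
}

#' Write / read a cohort as long-format CSV
#'
#' `write_cohort()` writes `observations.csv` (columns `participant_id,
#' modality, age_years, value`) and `truth.csv` (the ground-truth sidecar)
#' into a directory; `read_cohort()` reads them back. Round-trips are
#' lossless up to double-precision text round-trip (15 significant digits).
#'
#' @param cohort a `cohort` object (or, for plain data, a list with a `data`
#'   data frame; `truth` optional).
#' @param path directory to write into (created if needed).
#' @return `read_cohort()` returns a `cohort` object (with `truth = NULL` and
#'   `config = NULL` if no sidecar is present).
#' @export
write_cohort <- function(cohort, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  dat <- cohort$data
  dat$value <- format_num(dat$value)
  dat$age_years <- format_num(dat$age_years)
  utils::write.csv(dat, file.path(path, "observations.csv"), row.names = FALSE,
                   quote = FALSE)
  if (!is.null(cohort$truth)) {
    tr <- cohort$truth
    num <- vapply(tr, is.numeric, logical(1)) & !vapply(tr, is.integer, logical(1))
    tr[num] <- lapply(tr[num], format_num)
    utils::write.csv(tr, file.path(path, "truth.csv"), row.names = FALSE,
                     quote = FALSE)
  }
  invisible(path)
}

format_num <- function(x) {
  out <- formatC(x, digits = 15, format = "g")
  out[is.na(x)] <- "NA"
  out
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  obs_path <- file.path(path, "observations.csv")
  if (!file.exists(obs_path)) stop("no observations.csv under ", path, call. = FALSE)
  dat <- utils::read.csv(obs_path, stringsAsFactors = FALSE, comment.char = "#")
  needed <- c("participant_id", "modality", "age_years", "value")
  if (!all(needed %in% names(dat)))
    stop("observations.csv is missing required columns: ",
         paste(setdiff(needed, names(dat)), collapse = ", "), call. = FALSE)
  for (col in c("age_years", "value")) {
    if (is.character(dat[[col]])) {
      conv <- suppressWarnings(as.numeric(dat[[col]]))
      bad <- which(is.na(conv) & !is.na(dat[[col]]) & nzchar(dat[[col]]))
      if (length(bad))
        stop(sprintf("parse error in observations.csv line %d: non-numeric %s '%s'",
                     bad[1] + 1L, col, dat[[col]][bad[1]]), call. = FALSE)
      dat[[col]] <- conv
    }
  }
  bad <- which(!is.finite(dat$value) | !is.finite(dat$age_years))
  if (length(bad))
    stop(sprintf("parse error in observations.csv line %d: non-finite value", bad[1] + 1L),
         call. = FALSE)
  truth <- NULL
  tr_path <- file.path(path, "truth.csv")
  if (file.exists(tr_path))
    truth <- utils::read.csv(tr_path, stringsAsFactors = FALSE, comment.char = "#")
  structure(list(data = dat, truth = truth, config = NULL), class = "cohort")
}

#' Extract one participant-by-modality series from a long table
#'
#' @param data long-format observations (`participant_id, modality,
#'   age_years, value`).
#' @param participant_id,modality selectors.
#' @return data frame ordered by age.
#' @keywords internal
series_of <- function(data, participant_id, modality) {
  s <- data[data$participant_id == participant_id & data$modality == modality, ]
  s[order(s$age_years), ]
}
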