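#' Read a pipeline configuration file
#'
#' Reads a YAML configuration with optional blocks `simulate` (arguments to
#' [cohort_config()]), `input` (path to a cohort directory as written by
#' [write_cohort()]), `thresholding`, `sila`, `models`, `crossing` (per-stage
#' parameter overrides), `fixed_thresholds` (named modality thresholds that
#' are inputs rather than derived quantities, e.g. tau PET SUVR cuts), and
#' `seed`.
#'
#' @param path YAML file path.
#' @return a named list (class `pipeline_config`).
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "pipeline_config")
}

pipe_par <- function(cfg, block, name, default) {
  v <- cfg[[block]][[name]]
  if (is.null(v)) default else v
}

write_artifact <- function(df, path, stage, params, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# stage: %s", stage),
               sprintf("# software: biomclock %s",
                       as.character(utils::packageVersion("biomclock"))),
               sprintf("# seed: %s", seed),
               vapply(names(params), function(k)
                 sprintf("# %s: %s", k, paste(format(params[[k]], digits = 10),
                                              collapse = ",")),
                 character(1))), con)
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], format_num)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Select analysis subsets by declarative criteria
#'
#' Composes participant filters by conjunction. Supported criteria:
#' `"amyloid_positive"`, `"ptau_positive"`, `"dual_positive"` (positive on
#' both at last observation), `"tau_available"` (has tau PET observations),
#' `"converter_<modality>"` is not supported here (use
#' [validate_converters()]). An empty criteria vector selects everyone;
#' contradictory criteria yield an empty set without error.
#'
#' @param data long-format observations.
#' @param statuses named list of [classify_positivity()] tables, keyed by
#'   modality (`amyloid_dvr`, `ptau217_pgml` needed for positivity criteria).
#' @param criteria character vector of criterion names.
#' @return character vector of participant ids.
#' @export
subset_select <- function(data, statuses, criteria = character()) {
  ids <- unique(data$participant_id)
  pos_ids <- function(mod) {
    st <- statuses[[mod]]
    if (is.null(st)) stop("criterion needs positivity status for ", mod,
                          call. = FALSE)
    st$participant_id[st$status == "positive"]
  }
  for (cr in criteria) {
    sel <- switch(cr,
      amyloid_positive = pos_ids("amyloid_dvr"),
      ptau_positive = pos_ids("ptau217_pgml"),
      dual_positive = intersect(pos_ids("amyloid_dvr"), pos_ids("ptau217_pgml")),
      tau_available = unique(data$participant_id[
        data$modality %in% c("tau_ec_suvr", "tau_itg_suvr")]),
      stop("unknown subset criterion: ", cr, call. = FALSE))
    ids <- intersect(ids, sel)
  }
  ids
}

#' Run the full biomarker-timing analysis pipeline
#'
#' Executes, in order: cohort input (simulation or files), GBTM-derived
#' positivity thresholds for amyloid PET and plasma p-tau217, SILA curve
#' modelling and person-level onset estimation per modality, onset-timing
#' records, mixed-model comparisons of tau PET accumulation and cognitive
#' decline across time operationalizations, and delta-method crossing-time
#' estimates for downstream positivity. Every artefact CSV carries a
#' provenance header (stage parameters, seed, package version); identical
#' configuration and seed give byte-identical artefacts.
#'
#' @param config a `pipeline_config` (or plain list); see
#'   [read_pipeline_config()].
#' @param out_dir output directory for stage artefacts.
#' @param seed overrides `config$seed` when non-NULL.
#' @return (invisibly) a list of in-memory stage results: `cohort`,
#'   `thresholds`, `sila_fits`, `onsets`, `statuses`, `timing`,
#'   `tau_models`, `cognition`, `crossing`, `artifacts`.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  cfg <- config
  seed <- if (!is.null(seed)) seed else if (!is.null(cfg$seed)) cfg$seed else 1L
  if (is.null(cfg$simulate) && is.null(cfg$input))
    stop("config must provide either a 'simulate' block or an 'input' path",
         call. = FALSE)
  if (!is.null(cfg$input) && !dir.exists(cfg$input))
    stop("input path does not exist: ", cfg$input, call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  ## ---- input
  cohort <- stage("input", {
    if (!is.null(cfg$input)) read_cohort(cfg$input)
    else {
      sim_args <- cfg$simulate
      sim_args$seed <- seed
      simulate_cohort(do.call(cohort_config, sim_args))
    }
  })
  dat <- cohort$data
  core_mods <- intersect(c("amyloid_dvr", "ptau217_pgml"), unique(dat$modality))
  tau_mods <- intersect(c("tau_ec_suvr", "tau_itg_suvr"), unique(dat$modality))

  ## ---- thresholds (derived for core modalities, fixed for tau)
  n_groups <- pipe_par(cfg, "thresholding", "n_groups", NULL)
  t_order <- pipe_par(cfg, "thresholding", "order", 1)
  restarts <- pipe_par(cfg, "thresholding", "n_restarts", 10)
  thresholds <- list()
  assignments <- list()
  for (m in core_mods) {
    thr <- stage(paste0("thresholds:", m), {
      md <- dat[dat$modality == m, ]
      fit <- if (is.null(n_groups))
        gbtm_select(md, k_range = 1:4, order = t_order, n_restarts = restarts,
                    seed = seed)
      else gbtm(md, n_groups = n_groups, order = t_order,
                n_restarts = restarts, seed = seed)
      assignments[[m]] <- data.frame(participant_id = names(fit$assignment),
                                      group = unname(fit$assignment),
                                      posterior = fit$posterior[cbind(
                                        seq_len(nrow(fit$posterior)),
                                        fit$assignment)])
      derive_threshold(fit, md, modality = m)
    })
    thresholds[[m]] <- thr
  }
  fixed_thr <- cfg$fixed_thresholds
  if (is.null(fixed_thr)) fixed_thr <- list(tau_ec_suvr = 1.27, tau_itg_suvr = 1.42)
  thr_tab <- data.frame(
    modality = c(names(thresholds), intersect(tau_mods, names(fixed_thr))),
    threshold = c(vapply(thresholds, `[[`, numeric(1), "threshold"),
                  unlist(fixed_thr[intersect(tau_mods, names(fixed_thr))])),
    intercept = c(vapply(thresholds, `[[`, numeric(1), "nonaccumulator_intercept"),
                  rep(NA_real_, length(intersect(tau_mods, names(fixed_thr))))),
    q95_within_sd = c(vapply(thresholds, `[[`, numeric(1), "q95_within_person_sd"),
                      rep(NA_real_, length(intersect(tau_mods, names(fixed_thr))))),
    n_nonaccumulators = c(vapply(thresholds, `[[`, integer(1), "n_nonaccumulators"),
                          rep(NA_integer_, length(intersect(tau_mods, names(fixed_thr))))),
    row.names = NULL)
  artifacts <- c(artifacts, write_artifact(
    thr_tab, file.path(out_dir, "thresholds.csv"), "thresholds",
    list(n_groups = if (is.null(n_groups)) "BIC(1-4)" else n_groups,
         order = t_order, n_restarts = restarts, quantile = "type7 p95"), seed))
  for (m in names(assignments))
    artifacts <- c(artifacts, write_artifact(
      assignments[[m]], file.path(out_dir, paste0("gbtm_", m, ".csv")),
      "gbtm_assignments", list(modality = m), seed))

  ## ---- SILA + onsets + statuses
  sila_par <- list(dt = pipe_par(cfg, "sila", "dt", 0.05),
                   n_bins = pipe_par(cfg, "sila", "n_bins", 40),
                   min_per_bin = pipe_par(cfg, "sila", "min_per_bin", 3),
                   smooth_window = pipe_par(cfg, "sila", "smooth_window", 3),
                   rate_floor = pipe_par(cfg, "sila", "rate_floor", 1e-4))
  sila_fits <- list(); onsets <- list(); statuses <- list()
  for (m in core_mods) {
    md <- dat[dat$modality == m, ]
    sila_fits[[m]] <- stage(paste0("sila:", m),
      sila(md, thresholds[[m]], dt = sila_par$dt, n_bins = sila_par$n_bins,
           min_per_bin = sila_par$min_per_bin,
           smooth_window = sila_par$smooth_window,
           rate_floor = sila_par$rate_floor, modality = m))
    onsets[[m]] <- estimate_onset(sila_fits[[m]], md)
    statuses[[m]] <- classify_positivity(md, thresholds[[m]])
    artifacts <- c(artifacts, write_artifact(
      sila_fits[[m]]$curve, file.path(out_dir, paste0("curve_", m, ".csv")),
      "sila_curve", c(sila_par, threshold = thresholds[[m]]$threshold), seed))
    artifacts <- c(artifacts, write_artifact(
      onsets[[m]], file.path(out_dir, paste0("onsets_", m, ".csv")),
      "sila_onsets", c(sila_par, threshold = thresholds[[m]]$threshold), seed))
  }
  for (m in tau_mods) {
    md <- dat[dat$modality == m, ]
    statuses[[m]] <- classify_positivity(md, fixed_thr[[m]])
  }

  ## ---- onset timing
  timing <- NULL
  if (all(c("amyloid_dvr", "ptau217_pgml") %in% core_mods)) {
    timing <- stage("timing", build_timing_records(
      onsets$amyloid_dvr, onsets$ptau217_pgml,
      statuses$amyloid_dvr, statuses$ptau217_pgml))
    artifacts <- c(artifacts, write_artifact(
      as.data.frame(timing), file.path(out_dir, "timing.csv"), "timing",
      list(window = attr(timing, "window")), seed))
  }

  ## ---- longitudinal models
  mk_times <- function(md) {
    m_a <- match(md$participant_id, onsets$amyloid_dvr$participant_id)
    m_p <- match(md$participant_id, onsets$ptau217_pgml$participant_id)
    md$t_amyloid <- md$age_years - onsets$amyloid_dvr$onset_age[m_a]
    md$t_ptau <- md$age_years - onsets$ptau217_pgml$onset_age[m_p]
    md
  }
  dual <- subset_select(dat, statuses, "dual_positive")
  tau_models <- list()
  for (m in tau_mods) {
    md <- mk_times(dat[dat$modality == m & dat$participant_id %in% dual, ])
    if (length(unique(md$participant_id)) < 5) next
    tau_models[[m]] <- stage(paste0("models:", m), compare_time_models(
      md, "value",
      c(age = "age_years", amyloid_time = "t_amyloid", ptau_time = "t_ptau"),
      quadratic = FALSE))
    artifacts <- c(artifacts, write_artifact(
      tau_models[[m]]$table, file.path(out_dir, paste0("models_", m, ".csv")),
      "tau_models", list(outcome = m, quadratic = FALSE), seed))
  }
  cognition <- NULL
  if ("pacc3_z" %in% unique(dat$modality) && length(dual) >= 5) {
    cognition <- stage("models:cognition", {
      md <- mk_times(dat[dat$modality == "pacc3_z" & dat$participant_id %in% dual, ])
      md <- md[order(md$participant_id, md$age_years), ]
      first_age <- stats::ave(md$age_years, md$participant_id, FUN = min)
      md$baseline_age <- first_age
      md$exposures <- stats::ave(md$age_years, md$participant_id,
                                 FUN = seq_along) - 1
      if (!is.null(cohort$truth) && "sex" %in% names(cohort$truth)) {
        md$sex <- as.integer(cohort$truth$sex[
          match(md$participant_id, cohort$truth$participant_id)] == "female")
        covs <- c("baseline_age", "sex", "exposures")
      } else covs <- c("baseline_age", "exposures")
      cmp <- compare_time_models(
        md, "value",
        c(age = "age_years", amyloid_time = "t_amyloid", ptau_time = "t_ptau"),
        quadratic = TRUE, covariates = covs)
      rates <- do.call(rbind, lapply(c("amyloid_time", "ptau_time"), function(w) {
        r <- decline_rate_at(cmp$fits[[w]], c(5, 10))
        r$timeline <- w
        r
      }))
      list(comparison = cmp, decline_rates = rates)
    })
    artifacts <- c(artifacts, write_artifact(
      cognition$comparison$table, file.path(out_dir, "models_cognition.csv"),
      "cognition_models", list(quadratic = TRUE), seed))
    artifacts <- c(artifacts, write_artifact(
      cognition$decline_rates, file.path(out_dir, "decline_rates.csv"),
      "decline_rates", list(at_years = c(5, 10)), seed))
  }

  ## ---- crossing times (downstream positivity along each timeline)
  robust <- pipe_par(cfg, "crossing", "robust", TRUE)
  crossing <- list()
  a_pos <- subset_select(dat, statuses, "amyloid_positive")
  cross_specs <- list()
  if ("ptau217_pgml" %in% core_mods && "amyloid_dvr" %in% core_mods)
    cross_specs[["amyloid_time->ptau217_pgml"]] <-
      list(timeline = "amyloid_dvr", outcome = "ptau217_pgml",
           threshold = thresholds$ptau217_pgml$threshold)
  for (m in tau_mods) {
    cross_specs[[paste0("amyloid_time->", m)]] <-
      list(timeline = "amyloid_dvr", outcome = m, threshold = fixed_thr[[m]])
    cross_specs[[paste0("ptau_time->", m)]] <-
      list(timeline = "ptau217_pgml", outcome = m, threshold = fixed_thr[[m]])
  }
  for (nm in names(cross_specs)) {
    sp <- cross_specs[[nm]]
    md <- dat[dat$modality == sp$outcome & dat$participant_id %in% a_pos, ]
    on <- onsets[[sp$timeline]]
    tt <- md$age_years - on$onset_age[match(md$participant_id, on$participant_id)]
    est <- tryCatch({
      reg <- fit_crossing_regression(tt, md$value, cluster = md$participant_id,
                                     robust = robust)
      invert_to_threshold(reg, threshold = sp$threshold)
    }, error = function(e) NULL)
    if (!is.null(est)) crossing[[nm]] <- est
  }
  if (length(crossing)) {
    ct <- data.frame(comparison = names(crossing),
                     t_star = vapply(crossing, `[[`, numeric(1), "t_star"),
                     ci_low = vapply(crossing, function(e) e$ci95[1], numeric(1)),
                     ci_high = vapply(crossing, function(e) e$ci95[2], numeric(1)),
                     threshold = vapply(crossing, `[[`, numeric(1), "threshold"),
                     n = vapply(crossing, `[[`, numeric(1), "n"),
                     row.names = NULL)
    artifacts <- c(artifacts, write_artifact(
      ct, file.path(out_dir, "crossing_times.csv"), "crossing",
      list(robust = robust, ci = "Wald 1.96"), seed))
  }

  invisible(list(cohort = cohort, thresholds = thresholds,
                 sila_fits = sila_fits, onsets = onsets, statuses = statuses,
                 timing = timing, tau_models = tau_models,
                 cognition = cognition, crossing = crossing,
                 artifacts = artifacts, seed = seed, out_dir = out_dir))
}
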