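#' Identify the non-accumulating subset from a GBTM fit
#'
#' Starting from the members of the lowest-intercept trajectory group,
#' retains only participants with no observed value greater than or equal to
#' that group's intercept plus two intercept standard errors. This is the
#' first step of the two-step data-driven threshold procedure: it trims
#' borderline members so the retained set reflects stable, sub-threshold
#' measurement behaviour only.
#'
#' @param fit a [gbtm()] fit.
#' @param data the long-format observations the fit was derived from.
#' @param se_rule scale of the two-standard-error trim: `"residual_sd"`
#'   (default) uses the model's residual SD, so the cut is intercept + 2
#'   residual SDs and retains participants whose values all lie within
#'   ordinary measurement scatter of the group level; `"intercept_se"` uses
#'   the intercept's estimation SE. The estimation SE shrinks as 1/sqrt(n),
#'   so at cohort scale it trims nearly every member of the group (any
#'   single noisy observation exceeds the cut), which defeats the purpose of
#'   the rule; it is provided for strict-reading comparisons. The rule used
#'   is recorded in the result.
#' @return character vector of participant ids, with attribute `se_rule`.
#' @export
identify_nonaccumulators <- function(fit, data,
                                     se_rule = c("residual_sd", "intercept_se")) {
  stopifnot(inherits(fit, "gbtm"))
  se_rule <- match.arg(se_rule)
  members <- names(fit$assignment)[fit$assignment == 1L]
  scale2 <- if (se_rule == "residual_sd") fit$sigma else fit$se[1, 1]
  cut <- fit$coefficients[1, 1] + 2 * scale2
  keep <- vapply(members, function(p) {
    v <- data$value[data$participant_id == p]
    length(v) > 0 && all(v < cut)
  }, logical(1))
  out <- members[keep]
  if (!length(out))
    stop("no non-accumulating participants retained; ",
         "threshold derivation is impossible on this data", call. = FALSE)
  attr(out, "se_rule") <- se_rule
  out
}

#' Within-person standard deviations
#'
#' Sample SD (denominator n - 1) of each participant's observed values.
#' Participants with fewer than two observations are skipped with a message.
#'
#' @param data long-format observations for one modality.
#' @param participants optional subset of participant ids.
#' @return named numeric vector of SDs.
#' @export
within_person_sd <- function(data, participants = NULL) {
  if (!is.null(participants)) data <- data[data$participant_id %in% participants, ]
  vals <- split(data$value, data$participant_id)
  n <- lengths(vals)
  if (any(n < 2))
    message(sum(n < 2), " participant(s) with < 2 observations skipped in ",
            "within-person SD computation")
  vals <- vals[n >= 2]
  vapply(vals, stats::sd, numeric(1))
}

#' Derive a positivity threshold from the non-accumulating group
#'
#' Threshold = non-accumulating group intercept + 95th percentile of the
#' within-person SDs of the non-accumulating participants. The percentile
#' uses the linear-interpolation quantile (type 7); the choice is recorded in
#' the returned object.
#'
#' @param fit a [gbtm()] fit.
#' @param data long-format observations for the modality.
#' @param nonaccumulators participant ids, as from
#'   [identify_nonaccumulators()] (computed if `NULL`).
#' @param modality label stored in the result.
#' @param prob percentile of the within-person SDs (default 0.95).
#' @return object of class `positivity_threshold` with fields `modality`,
#'   `threshold`, `nonaccumulator_intercept`, `q95_within_person_sd`,
#'   `n_nonaccumulators`, `quantile_type`, `prob`.
#' @export
derive_threshold <- function(fit, data, nonaccumulators = NULL,
                             modality = NA_character_, prob = 0.95) {
  stopifnot(inherits(fit, "gbtm"))
  if (is.null(nonaccumulators))
    nonaccumulators <- identify_nonaccumulators(fit, data)
  if (!length(nonaccumulators))
    stop("empty non-accumulator set", call. = FALSE)
  sds <- within_person_sd(data, nonaccumulators)
  if (!length(sds))
    stop("no non-accumulators with >= 2 observations", call. = FALSE)
  q95 <- unname(stats::quantile(sds, prob, type = 7))
  intercept <- fit$coefficients[1, 1]
  structure(list(modality = modality,
                 threshold = intercept + q95,
                 nonaccumulator_intercept = intercept,
                 q95_within_person_sd = q95,
                 n_nonaccumulators = length(sds),
                 quantile_type = 7L, prob = prob,
                 se_rule = attr(nonaccumulators, "se_rule")),
            class = "positivity_threshold")
}

#' @export
print.positivity_threshold <- function(x, ...) {
  cat(sprintf("Positivity threshold%s: %.4g\n",
              if (is.na(x$modality)) "" else paste0(" (", x$modality, ")"),
              x$threshold))
  cat(sprintf("  = non-accumulator intercept %.4g + %g%% within-person SD %.4g\n",
              x$nonaccumulator_intercept, 100 * x$prob, x$q95_within_person_sd))
  cat(sprintf("  n non-accumulators: %d (quantile type %d)\n",
              x$n_nonaccumulators, x$quantile_type))
  invisible(x)
}

#' Classify biomarker positivity
#'
#' A participant is biomarker-positive if the value at their most recent
#' observation strictly exceeds the threshold. The first-positive age is the
#' age of the earliest observation strictly above threshold (NA if never
#' observed above).
#'
#' @param data long-format observations for one modality.
#' @param threshold numeric threshold or a `positivity_threshold` object.
#' @return data frame: `participant_id`, `status` ("positive"/"negative"),
#'   `last_age`, `last_value`, `first_positive_age`.
#' @export
classify_positivity <- function(data, threshold) {
  thr <- if (inherits(threshold, "positivity_threshold")) threshold$threshold else threshold
  sp <- split(data, data$participant_id)
  out <- lapply(sp, function(s) {
    s <- s[order(s$age_years), ]
    pos <- s$value > thr
    data.frame(participant_id = s$participant_id[1],
               status = if (pos[nrow(s)]) "positive" else "negative",
               last_age = s$age_years[nrow(s)],
               last_value = s$value[nrow(s)],
               first_positive_age = if (any(pos)) s$age_years[which(pos)[1]] else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
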