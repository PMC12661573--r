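#' Build person-level onset timing records for two biomarkers
#'
#' Joins amyloid and p-tau217 onset estimates and computes the onset delta
#' (p-tau217 onset age minus amyloid onset age) for participants who are
#' positive on both biomarkers at their last available observation
#' (dual-positive). Others carry no delta and are labelled `indeterminate`.
#'
#' @param amyloid_onsets,ptau_onsets `sila_onsets` data frames (one row per
#'   participant; duplicates are an error).
#' @param amyloid_status,ptau_status data frames from
#'   [classify_positivity()]; when `NULL`, the `observed_positive` flag of
#'   the onset tables is used.
#' @param window coincidence window in years for [classify_timing_group()].
#' @return data frame of class `timing_records`: `participant_id,
#'   amyloid_onset_age, ptau_onset_age, delta_A_to_ptau, timing_group`.
#' @export
build_timing_records <- function(amyloid_onsets, ptau_onsets,
                                 amyloid_status = NULL, ptau_status = NULL,
                                 window = 2) {
  for (tab in list(amyloid_onsets, ptau_onsets))
    if (anyDuplicated(tab$participant_id))
      stop("duplicate participant_id in onset table", call. = FALSE)
  pos_flag <- function(onsets, status) {
    if (is.null(status)) {
      stats::setNames(onsets$observed_positive, onsets$participant_id)
    } else {
      stats::setNames(status$status == "positive", status$participant_id)
    }
  }
  pos_a <- pos_flag(amyloid_onsets, amyloid_status)
  pos_p <- pos_flag(ptau_onsets, ptau_status)
  ids <- union(amyloid_onsets$participant_id, ptau_onsets$participant_id)
  ma <- match(ids, amyloid_onsets$participant_id)
  mp <- match(ids, ptau_onsets$participant_id)
  rec <- data.frame(participant_id = ids,
                    amyloid_onset_age = amyloid_onsets$onset_age[ma],
                    ptau_onset_age = ptau_onsets$onset_age[mp],
                    stringsAsFactors = FALSE)
  dual <- !is.na(ma) & !is.na(mp) &
    ids %in% names(pos_a)[pos_a] & ids %in% names(pos_p)[pos_p]
  rec$delta_A_to_ptau <- ifelse(dual, rec$ptau_onset_age - rec$amyloid_onset_age,
                                NA_real_)
  rec$timing_group <- ifelse(dual,
                             classify_timing_group(rec$delta_A_to_ptau, window),
                             "indeterminate")
  class(rec) <- c("timing_records", "data.frame")
  attr(rec, "window") <- window
  rec
}

#' Classify the relative timing of two biomarker onsets
#'
#' Onsets within `window` years of each other (inclusive) are `coincident`;
#' a delta (p-tau onset minus amyloid onset) above the window is `A_first`;
#' below the negative window is `ptau_first`.
#'
#' @param delta numeric vector of onset deltas in years.
#' @param window coincidence half-width in years (default 2).
#' @return character vector.
#' @export
classify_timing_group <- function(delta, window = 2) {
  out <- rep(NA_character_, length(delta))
  out[!is.na(delta) & abs(delta) <= window] <- "coincident"
  out[!is.na(delta) & delta > window] <- "A_first"
  out[!is.na(delta) & delta < -window] <- "ptau_first"
  out
}

#' Correlate an onset age with the onset delta
#'
#' Pearson correlation (with two-sided t-test) between one biomarker's onset
#' age and the time interval between amyloid and p-tau217 onset, over
#' dual-positive records.
#'
#' @param records a `timing_records` data frame.
#' @param which onset to correlate: `"amyloid"` or `"ptau"`.
#' @return list `r`, `p_value`, `n`.
#' @export
correlate_onset_with_delta <- function(records, which = c("amyloid", "ptau")) {
  which <- match.arg(which)
  rec <- records[!is.na(records$delta_A_to_ptau), ]
  if (nrow(rec) < 3) stop("need >= 3 dual-positive records", call. = FALSE)
  x <- if (which == "amyloid") rec$amyloid_onset_age else rec$ptau_onset_age
  y <- rec$delta_A_to_ptau
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = nrow(rec))
}

#' Compare onset ages across a two-level grouping
#'
#' Welch two-sample t-test (unequal variances) of onset ages across sex or
#' APOE-e4 carriage (or any two-level factor).
#'
#' @param onset_age numeric vector of onset ages.
#' @param group factor-like vector with exactly two levels.
#' @return list `t`, `df`, `p_value`, `means` (named group means).
#' @export
compare_onset_by_group <- function(onset_age, group) {
  keep <- !is.na(onset_age) & !is.na(group)
  onset_age <- onset_age[keep]; group <- factor(group[keep])
  if (nlevels(group) != 2) stop("grouping must have exactly two levels", call. = FALSE)
  if (any(table(group) < 2)) stop("each group needs >= 2 onset ages", call. = FALSE)
  tt <- stats::t.test(onset_age ~ group, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value,
       means = stats::setNames(as.numeric(tapply(onset_age, group, mean)),
                               levels(group)))
}
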