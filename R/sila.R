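#' Per-participant biomarker accumulation rates
#'
#' For every participant with at least `min_obs` observations, the rate is
#' the OLS slope of value versus age and the mid-value is the mean of the
#' observed values. Participants with fewer observations contribute no rate
#' point (they are excluded from curve modelling only, not from onset
#' estimation).
#'
#' @param data long-format observations for one modality.
#' @param min_obs minimum observations required (>= 2).
#' @return data frame `participant_id, mid_value, rate, n_obs`.
#' @export
estimate_rates <- function(data, min_obs = 2) {
  stopifnot(min_obs >= 2)
  sp <- split(data, data$participant_id)
  sp <- sp[vapply(sp, nrow, integer(1)) >= min_obs]
  if (!length(sp))
    stop("no participants with >= ", min_obs,
         " observations; cannot model accumulation rates", call. = FALSE)
  out <- lapply(sp, function(s) {
    fit <- stats::lm.fit(cbind(1, s$age_years), s$value)
    data.frame(participant_id = s$participant_id[1],
               mid_value = mean(s$value),
               rate = unname(fit$coefficients[2]),
               n_obs = nrow(s), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Discretely sample the rate-versus-value curve
#'
#' Bins per-participant (mid-value, rate) points into equal-width value bins,
#' averages the rates per bin, fills bins below the occupancy minimum by
#' linear interpolation between occupied neighbours (nearest occupied bin at
#' the edges), smooths with a centred moving mean, and clamps the smoothed
#' rates at a strictly positive floor so the curve can be integrated through
#' sub-threshold plateaus.
#'
#' @param rates data frame from [estimate_rates()].
#' @param n_bins number of equal-width value bins.
#' @param min_per_bin minimum contributing participants per bin.
#' @param smooth_window moving-average window in bins (odd; 1 = none).
#' @param rate_floor lower clamp for the smoothed rate (units/year).
#' @param value_range range to bin over (default: observed mid-value range).
#' @return data frame of class `rate_samples`: `bin_center, mean_rate,
#'   n_contributing, rate_sd, interpolated`.
#' @export
sample_rate_curve <- function(rates, n_bins = 40, min_per_bin = 3,
                              smooth_window = 3, rate_floor = 1e-4,
                              value_range = NULL) {
  if (is.null(value_range)) value_range <- range(rates$mid_value)
  if (diff(value_range) <= 0)
    value_range <- value_range + c(-1, 1) * max(1e-6, abs(value_range[1]) * 1e-3)
  breaks <- seq(value_range[1], value_range[2], length.out = n_bins + 1)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  bin <- findInterval(rates$mid_value, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  n_in <- tabulate(bin, n_bins)
  mean_r <- rep(NA_real_, n_bins)
  sd_r <- rep(NA_real_, n_bins)
  agg <- tapply(rates$rate, factor(bin, levels = seq_len(n_bins)), mean)
  sds <- tapply(rates$rate, factor(bin, levels = seq_len(n_bins)), stats::sd)
  mean_r[] <- as.numeric(agg)
  sd_r[] <- as.numeric(sds)
  ok <- n_in >= min_per_bin
  if (!any(ok))
    stop("no value bin reaches the minimum of ", min_per_bin,
         " contributing participants", call. = FALSE)
  # interpolate under-occupied bins between occupied neighbours
  filled <- stats::approx(centers[ok], mean_r[ok], xout = centers, rule = 2)$y
  mean_r[!ok] <- filled[!ok]
  # centred moving mean
  if (smooth_window > 1) {
    k <- smooth_window %/% 2
    sm <- vapply(seq_len(n_bins), function(i) {
      j <- max(1, i - k):min(n_bins, i + k)
      mean(mean_r[j])
    }, numeric(1))
    mean_r <- sm
  }
  mean_r <- pmax(mean_r, rate_floor)
  structure(data.frame(bin_center = centers, mean_rate = mean_r,
                       n_contributing = n_in, rate_sd = sd_r,
                       interpolated = !ok),
            class = c("rate_samples", "data.frame"),
            rate_floor = rate_floor)
}

rate_interpolator <- function(samples) {
  x <- samples$bin_center
  y <- samples$mean_rate
  function(v) stats::approx(x, y, xout = v, rule = 2)$y
}

#' Euler-integrate a sampled rate curve into a value-versus-time curve
#'
#' Integrates \eqn{dv/dt = r(v)} with the forward Euler scheme from the
#' anchor point (time 0, value = threshold): forward with step `dt` until the
#' upper domain bound and backward with step `-dt` until the lower bound.
#' Rates at arbitrary values are linearly interpolated between bin centres
#' (constant beyond the ends). Time zero on the resulting curve is the
#' positivity threshold crossing.
#'
#' @param samples `rate_samples` from [sample_rate_curve()], or any data
#'   frame with `bin_center` and `mean_rate` columns.
#' @param threshold positivity threshold (must lie inside `domain`).
#' @param dt Euler step in years.
#' @param domain value bounds `c(lower, upper)` to integrate over.
#' @param max_span hard cap, in years, on each limb of the curve (guards
#'   against unbounded integration across rate-floor plateaus).
#' @return object of class `sila_curve`: data frame `time, value` (uniform
#'   time grid with spacing `dt`, value strictly increasing), with the
#'   threshold, `dt` and domain stored as attributes.
#' @export
integrate_curve <- function(samples, threshold, dt = 0.05,
                            domain = range(samples$bin_center),
                            max_span = 500) {
  stopifnot(dt > 0)
  if (threshold < domain[1] || threshold > domain[2])
    stop("threshold must lie inside the integration domain", call. = FALSE)
  r <- rate_interpolator(samples)
  step_until <- function(sign, bound_test) {
    n_max <- ceiling(max_span / dt)
    vs <- numeric(n_max); ts <- numeric(n_max)
    v <- threshold; t <- 0
    k <- 0L
    repeat {
      rate <- r(v)
      if (!is.finite(rate) || rate <= 0)
        stop(sprintf("non-positive rate %.3g encountered at value %.4g",
                     rate, v), call. = FALSE)
      v2 <- v + sign * rate * dt
      t2 <- t + sign * dt
      if (bound_test(v2) || k >= n_max) break
      k <- k + 1L
      vs[k] <- v2; ts[k] <- t2
      v <- v2; t <- t2
    }
    list(t = ts[seq_len(k)], v = vs[seq_len(k)])
  }
  fwd <- step_until(1, function(v) v > domain[2])
  bwd <- step_until(-1, function(v) v < domain[1])
  tt <- c(rev(bwd$t), 0, fwd$t)
  vv <- c(rev(bwd$v), threshold, fwd$v)
  if (any(diff(vv) <= 0))
    stop("integrated curve is not strictly increasing", call. = FALSE)
  structure(data.frame(time = tt, value = vv),
            class = c("sila_curve", "data.frame"),
            threshold = threshold, dt = dt, domain = domain)
}

#' Invert a modelled curve: value to time-since-threshold
#'
#' Monotone linear interpolation of the (value -> time) mapping of a
#' `sila_curve`. Values beyond the curve's range are mapped by extending the
#' terminal slope when `extrapolate = TRUE` (the result is flagged),
#' otherwise an error is raised.
#'
#' @param curve a `sila_curve` from [integrate_curve()].
#' @param value numeric vector of biomarker values.
#' @param extrapolate allow values outside the curve's range.
#' @return numeric vector of times since threshold (years; negative =
#'   pre-onset), with attribute `extrapolated` (logical vector).
#' @export
invert_curve <- function(curve, value, extrapolate = TRUE) {
  vv <- curve$value; tt <- curve$time
  out <- stats::approx(vv, tt, xout = value, rule = 2)$y
  lo <- value < vv[1]; hi <- value > vv[length(vv)]
  extra <- lo | hi
  if (any(extra)) {
    if (!extrapolate)
      stop("value outside the modelled curve range and extrapolation is disabled",
           call. = FALSE)
    n <- length(vv)
    slope_lo <- (tt[2] - tt[1]) / (vv[2] - vv[1])
    slope_hi <- (tt[n] - tt[n - 1]) / (vv[n] - vv[n - 1])
    out[lo] <- tt[1] + (value[lo] - vv[1]) * slope_lo
    out[hi] <- tt[n] + (value[hi] - vv[n]) * slope_hi
  }
  attr(out, "extrapolated") <- extra
  out
}

#' Value on a modelled curve at a given time since threshold
#'
#' Linear interpolation of the (time -> value) mapping, extending the
#' terminal slope outside the modelled time range.
#'
#' @param curve a `sila_curve`.
#' @param time numeric vector of times since threshold (years).
#' @return numeric vector of modelled values.
#' @export
curve_value_at <- function(curve, time) {
  tt <- curve$time; vv <- curve$value
  out <- stats::approx(tt, vv, xout = time, rule = 2)$y
  n <- length(tt)
  lo <- time < tt[1]; hi <- time > tt[n]
  if (any(lo)) out[lo] <- vv[1] + (time[lo] - tt[1]) * (vv[2] - vv[1]) / (tt[2] - tt[1])
  if (any(hi)) out[hi] <- vv[n] + (time[hi] - tt[n]) * (vv[n] - vv[n - 1]) / (tt[n] - tt[n - 1])
  out
}

#' Reference observation for onset estimation
#'
#' The reference observation is the participant's first observation after
#' crossing the positivity threshold if they were observed biomarker-positive
#' during the study, or their last observation if they remained
#' biomarker-negative throughout. Using the first supra-threshold observation
#' avoids extrapolating beyond the observed data at the top of the value
#' distribution.
#'
#' @param series one participant's observations (`age_years`, `value`).
#' @param threshold positivity threshold.
#' @return list `age`, `value`, `observed_positive`.
#' @export
select_reference_observation <- function(series, threshold) {
  s <- series[order(series$age_years), ]
  pos <- s$value > threshold
  if (any(pos)) {
    i <- which(pos)[1]
    list(age = s$age_years[i], value = s$value[i], observed_positive = TRUE)
  } else {
    n <- nrow(s)
    list(age = s$age_years[n], value = s$value[n], observed_positive = FALSE)
  }
}

#' Fit a SILA accumulation model
#'
#' Sampled iterative local approximation (SILA) models a biomarker's
#' accumulation rate as a function of its value and integrates the sampled
#' rate-versus-value curve (forward Euler) into a single value-versus-time
#' curve anchored with time zero at the positivity threshold. Person-level
#' onset ages are then obtained by aligning each participant's reference
#' observation to the curve (see [estimate_onset()] / `predict.sila`).
#'
#' @param data long-format observations for one modality.
#' @param threshold positivity threshold (numeric or `positivity_threshold`).
#' @param min_obs minimum observations per participant for rate estimation.
#' @param n_bins,min_per_bin,smooth_window,rate_floor see
#'   [sample_rate_curve()].
#' @param dt Euler step in years.
#' @param domain_quantiles value-domain quantiles; the integration domain is
#'   the observed value range between these quantiles, extended to include
#'   the threshold.
#' @param modality optional label.
#' @return object of class `sila`: list with `curve` (`sila_curve`),
#'   `rate_samples`, `rates`, `threshold`, `modality` and the tuning
#'   parameters.
#' @examples
#' coh <- simulate_cohort(cohort_config(n_participants = 80, seed = 3))
#' amy <- coh$data[coh$data$modality == "amyloid_dvr", ]
#' fit <- sila(amy, threshold = 1.14, modality = "amyloid_dvr")
#' onsets <- predict(fit, amy)
#' head(onsets)
#' @export
sila <- function(data, threshold, min_obs = 2, n_bins = 40, min_per_bin = 3,
                 smooth_window = 3, rate_floor = 1e-4, dt = 0.05,
                 domain_quantiles = c(0.025, 0.975), modality = NA_character_) {
  thr <- if (inherits(threshold, "positivity_threshold")) threshold$threshold else threshold
  rates <- estimate_rates(data, min_obs = min_obs)
  samples <- sample_rate_curve(rates, n_bins = n_bins, min_per_bin = min_per_bin,
                               smooth_window = smooth_window,
                               rate_floor = rate_floor)
  dom <- unname(stats::quantile(data$value, domain_quantiles, type = 7))
  dom[1] <- min(dom[1], thr - dt * rate_floor)
  dom[2] <- max(dom[2], thr + dt * rate_floor)
  curve <- integrate_curve(samples, thr, dt = dt, domain = dom)
  structure(list(curve = curve, rate_samples = samples, rates = rates,
                 threshold = thr, modality = modality,
                 params = list(min_obs = min_obs, n_bins = n_bins,
                               min_per_bin = min_per_bin,
                               smooth_window = smooth_window,
                               rate_floor = rate_floor, dt = dt,
                               domain_quantiles = domain_quantiles)),
            class = "sila")
}

#' @export
print.sila <- function(x, ...) {
  cat(sprintf("SILA accumulation model%s\n",
              if (is.na(x$modality)) "" else paste0(" (", x$modality, ")")))
  cat(sprintf("  threshold (time 0): %.4g; Euler dt %.3g y\n", x$threshold,
              attr(x$curve, "dt")))
  cat(sprintf("  curve spans %.1f to %.1f years since threshold (values %.4g-%.4g)\n",
              min(x$curve$time), max(x$curve$time),
              min(x$curve$value), max(x$curve$value)))
  cat(sprintf("  rate points: %d participants; %d value bins\n",
              nrow(x$rates), nrow(x$rate_samples)))
  invisible(x)
}

#' @export
plot.sila <- function(x, which = c("curve", "rates"), ...) {
  which <- match.arg(which)
  if (which == "curve") {
    graphics::plot(x$curve$time, x$curve$value, type = "l",
                   xlab = "Years since threshold", ylab = "Biomarker value",
                   main = "SILA modelled accumulation curve", ...)
    graphics::abline(h = x$threshold, lty = 2)
    graphics::abline(v = 0, lty = 3, col = "grey")
  } else {
    graphics::plot(x$rates$mid_value, x$rates$rate, pch = 16,
                   col = "grey60", xlab = "Biomarker value",
                   ylab = "Rate (units/year)",
                   main = "Sampled rate vs value", ...)
    graphics::lines(x$rate_samples$bin_center, x$rate_samples$mean_rate, lwd = 2)
  }
  invisible(x)
}

#' Estimate person-level biomarker onset ages
#'
#' Aligns each participant's reference observation (see
#' [select_reference_observation()]) to the modelled curve: the positive time
#' at the reference is the curve time at the reference value, and the onset
#' age is the reference age minus that positive time. Participants whose
#' reference value falls outside the modelled curve are aligned by terminal-
#' slope extrapolation and flagged.
#'
#' @param fit a `sila` fit.
#' @param data long-format observations (any number of participants).
#' @return data frame of class `sila_onsets`: `participant_id, modality,
#'   reference_age, reference_value, positive_time_at_reference, onset_age,
#'   observed_positive, extrapolated`.
#' @export
estimate_onset <- function(fit, data) {
  stopifnot(inherits(fit, "sila"))
  sp <- split(data, data$participant_id)
  out <- lapply(sp, function(s) {
    ref <- select_reference_observation(s, fit$threshold)
    t_ref <- invert_curve(fit$curve, ref$value, extrapolate = TRUE)
    data.frame(participant_id = s$participant_id[1],
               modality = fit$modality,
               reference_age = ref$age,
               reference_value = ref$value,
               positive_time_at_reference = as.numeric(t_ref),
               onset_age = ref$age - as.numeric(t_ref),
               observed_positive = ref$observed_positive,
               extrapolated = attr(t_ref, "extrapolated")[1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("sila_onsets", "data.frame")
  out
}

#' @rdname estimate_onset
#' @param object a `sila` fit.
#' @param newdata long-format observations.
#' @param ... unused.
#' @export
predict.sila <- function(object, newdata, ...) estimate_onset(object, newdata)

#' Modelled biomarker value for a participant at a given age
#'
#' Evaluates the fitted curve at `age - onset_age`, i.e. the modelled level
#' the participant is expected to have at that age given their estimated
#' onset. Used e.g. to carry SILA-estimated levels to the date of a tau PET
#' scan.
#'
#' @param fit a `sila` fit.
#' @param onsets `sila_onsets` for the participants of interest.
#' @param ages named numeric vector or data frame (`participant_id, age`)
#'   of ages at which to evaluate.
#' @return data frame `participant_id, age, biomarker_time, value`.
#' @export
estimate_value_at <- function(fit, onsets, ages) {
  if (is.data.frame(ages)) {
    ids <- ages$participant_id; aa <- ages$age
  } else {
    ids <- names(ages); aa <- as.numeric(ages)
  }
  m <- match(ids, onsets$participant_id)
  if (anyNA(m)) stop("ages supplied for participants without onset estimates",
                     call. = FALSE)
  bt <- aa - onsets$onset_age[m]
  data.frame(participant_id = ids, age = aa, biomarker_time = bt,
             value = curve_value_at(fit$curve, bt), stringsAsFactors = FALSE)
}

#' Root-mean-squared error of SILA concentration estimation
#'
#' RMSE over all observations between the observed value and the modelled
#' value at the observation age implied by each participant's estimated
#' onset.
#'
#' @param fit a `sila` fit.
#' @param data long-format observations.
#' @param onsets `sila_onsets`; computed from `data` if missing.
#' @return single numeric RMSE in modality units.
#' @export
concentration_rmse <- function(fit, data, onsets = NULL) {
  if (is.null(onsets)) onsets <- estimate_onset(fit, data)
  m <- match(data$participant_id, onsets$participant_id)
  keep <- !is.na(m)
  bt <- data$age_years[keep] - onsets$onset_age[m[keep]]
  pred <- curve_value_at(fit$curve, bt)
  sqrt(mean((data$value[keep] - pred)^2))
}

#' Validate onset estimates against observed converters
#'
#' For participants observed to cross the threshold between consecutive
#' visits (converters), compares the SILA-estimated onset age with the age
#' midpoint between the last sub-threshold and first supra-threshold
#' observation. Returns the mean difference (estimated minus midpoint) with
#' a normal-theory 95% confidence interval.
#'
#' @param data long-format observations.
#' @param onsets `sila_onsets` for the same modality.
#' @param threshold positivity threshold.
#' @return list `mean_difference`, `ci` (length-2), `n`, `differences`
#'   (per-converter data frame); all `NA`/empty with a message when no
#'   converters exist.
#' @export
validate_converters <- function(data, onsets, threshold) {
  thr <- if (inherits(threshold, "positivity_threshold")) threshold$threshold else threshold
  sp <- split(data, data$participant_id)
  rows <- lapply(sp, function(s) {
    s <- s[order(s$age_years), ]
    pos <- s$value > thr
    i <- which(pos)[1]
    if (is.na(i) || i == 1L) return(NULL)   # never positive, or positive at entry
    if (any(pos[seq_len(i - 1)])) return(NULL)
    data.frame(participant_id = s$participant_id[1],
               last_negative_age = s$age_years[i - 1],
               first_positive_age = s$age_years[i],
               midpoint_age = (s$age_years[i - 1] + s$age_years[i]) / 2,
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || !nrow(rows)) {
    message("no observed converters; midpoint validation unavailable")
    return(list(mean_difference = NA_real_, ci = c(NA_real_, NA_real_),
                n = 0L, differences = NULL))
  }
  m <- match(rows$participant_id, onsets$participant_id)
  rows$estimated_onset_age <- onsets$onset_age[m]
  rows$difference <- rows$estimated_onset_age - rows$midpoint_age
  n <- nrow(rows)
  mu <- mean(rows$difference)
  se <- if (n > 1) stats::sd(rows$difference) / sqrt(n) else 0
  list(mean_difference = mu, ci = mu + c(-1.96, 1.96) * se, n = n,
       differences = rows)
}
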