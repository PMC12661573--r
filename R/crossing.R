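#' Linear regression of an outcome biomarker on biomarker time
#'
#' OLS fit of outcome values (e.g. plasma p-tau217 concentration or regional
#' tau PET SUVR at the scan date) on a biomarker timeline (years of amyloid-
#' or p-tau217-positivity), with either classical or cluster-robust (by
#' participant) coefficient covariance. Longitudinal designs with repeated
#' observations per participant default to the cluster-robust covariance.
#'
#' @param x predictor (biomarker time in years, or a SILA-estimated level).
#' @param y outcome values.
#' @param cluster optional participant ids for cluster-robust covariance.
#' @param robust use cluster-robust covariance (default: `TRUE` when
#'   `cluster` is supplied).
#' @return object of class `crossing_regression`: list `beta0`, `beta1`,
#'   `vcov` (2x2), `n`, `robust`, `model` (the `lm` fit).
#' @export
fit_crossing_regression <- function(x, y, cluster = NULL,
                                    robust = !is.null(cluster)) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (!is.null(cluster)) cluster <- cluster[keep]
  if (length(x) < 3) stop("need >= 3 observations", call. = FALSE)
  if (stats::sd(x) == 0) stop("degenerate predictor: zero variance", call. = FALSE)
  fit <- stats::lm(y ~ x)
  V <- if (robust) {
    if (is.null(cluster)) stop("cluster ids required for robust covariance",
                               call. = FALSE)
    sandwich::vcovCL(fit, cluster = cluster)
  } else stats::vcov(fit)
  structure(list(beta0 = unname(stats::coef(fit)[1]),
                 beta1 = unname(stats::coef(fit)[2]),
                 vcov = unname(as.matrix(V)), n = length(x),
                 robust = robust, model = fit),
            class = "crossing_regression")
}

#' Invert a fitted regression to a threshold-crossing time
#'
#' Given the fitted line `y = beta0 + beta1 t` of an outcome biomarker on a
#' biomarker timeline, the average time at which the outcome crosses its
#' positivity threshold is `t* = (threshold - beta0) / beta1`. Its variance
#' follows by the delta method with gradient
#' `g = (-1/beta1, -(threshold - beta0)/beta1^2)`, and the Wald interval is
#' `t* +/- 1.96 sqrt(g' V g)`.
#'
#' @param object a `crossing_regression`, or `beta0` as a number.
#' @param beta1,vcov coefficients and 2x2 covariance (when not passing a
#'   fitted object).
#' @param threshold outcome positivity threshold.
#' @param eps identifiability guard: `|beta1|` at or below `eps` is an error
#'   (a near-flat regression gives meaningless multi-century crossings).
#' @param conf_mult normal multiplier for the interval (1.96 for 95%).
#' @return object of class `crossing_estimate`: `t_star`, `se`,
#'   `ci95 = c(low, high)`, `threshold`, `beta0`, `beta1`, `vcov`, `n`.
#' @export
invert_to_threshold <- function(object, beta1 = NULL, vcov = NULL,
                                threshold, eps = 1e-6, conf_mult = 1.96) {
  if (inherits(object, "crossing_regression")) {
    beta0 <- object$beta0; beta1 <- object$beta1; vcov <- object$vcov
    n <- object$n
  } else {
    beta0 <- object; n <- NA_integer_
  }
  if (abs(beta1) <= eps)
    stop("crossing time unidentifiable: |slope| <= ", eps, call. = FALSE)
  t_star <- (threshold - beta0) / beta1
  g <- c(-1 / beta1, -(threshold - beta0) / beta1^2)
  v <- drop(t(g) %*% vcov %*% g)
  se <- sqrt(max(v, 0))
  structure(list(t_star = t_star, se = se,
                 ci95 = t_star + c(-1, 1) * conf_mult * se,
                 threshold = threshold, beta0 = beta0, beta1 = beta1,
                 vcov = vcov, n = n),
            class = "crossing_estimate")
}

#' @rdname invert_to_threshold
#' @details `crossing_level()` is the identical computation with the
#'   predictor being a SILA-estimated biomarker level (e.g. amyloid DVR or
#'   centiloid) instead of a time: the returned estimate is the predictor
#'   level at which the outcome crosses its threshold on average.
#' @export
crossing_level <- invert_to_threshold

#' @export
print.crossing_estimate <- function(x, ...) {
  cat(sprintf("Threshold crossing: t* = %.3g (95%% CI %.3g to %.3g)\n",
              x$t_star, x$ci95[1], x$ci95[2]))
  cat(sprintf("  outcome threshold %.4g; line y = %.4g + %.4g t; n = %s\n",
              x$threshold, x$beta0, x$beta1,
              ifelse(is.na(x$n), "?", x$n)))
  invisible(x)
}
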