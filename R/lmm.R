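#' Fit a linear mixed-effects model under a chosen time operationalization
#'
#' Fits `outcome ~ time (+ time^2) + covariates` with correlated random
#' intercept and time slope per participant, by maximum likelihood (ML, not
#' REML, so that AICc and likelihood-ratio tests comparing fixed-effects
#' structures are valid). The time variable is mean-centred within the
#' analysis data before entry; the centring constant is stored and used by
#' [decline_rate_at()].
#'
#' @param data data frame with one row per observation.
#' @param outcome,time column names of the outcome and the time variable
#'   (age, amyloid-positive time, or p-tau217-positive time, in years).
#' @param quadratic include a quadratic time term.
#' @param covariates character vector of additional fixed-effect columns.
#' @param id column holding the participant identifier.
#' @return object of class `lmm_fit`: list with the `lme4` fit (`model`),
#'   `logLik` (ML), `n_obs`, `n_parameters` (fixed effects + variance
#'   components), `time_center`, `time`, `quadratic`, `diagonal_re` flag.
#' @details A singular correlated random-effects fit is refit with
#'   independent (diagonal) intercept and slope and flagged. The parameter
#'   count includes all variance/covariance components and the residual
#'   variance, so AICc is auditable from `logLik`, `n_parameters`, `n_obs`.
#' @export
fit_lmm <- function(data, outcome, time, quadratic = FALSE,
                    covariates = character(), id = "participant_id") {
  stopifnot(all(c(outcome, time, covariates, id) %in% names(data)))
  d <- data[stats::complete.cases(data[c(outcome, time, covariates, id)]), ]
  ctr <- mean(d[[time]])
  d$.t <- d[[time]] - ctr
  d$.id <- d[[id]]
  fixed <- c(".t", if (quadratic) "I(.t^2)", covariates)
  form <- stats::as.formula(paste(outcome, "~", paste(fixed, collapse = " + "),
                                  "+ (1 + .t | .id)"))
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            optimizer = "bobyqa")
  fit <- suppressMessages(lme4::lmer(form, data = d, REML = FALSE, control = ctrl))
  # a singular intercept-slope correlation is refit with independent
  # (diagonal) random effects, but only adopted when the correlation was
  # genuinely unidentified (no likelihood lost) -- otherwise likelihoods
  # would stop being comparable across fits of the same data
  diagonal <- FALSE
  if (lme4::isSingular(fit, tol = 1e-4)) {
    form2 <- stats::as.formula(paste(outcome, "~",
                                     paste(fixed, collapse = " + "),
                                     "+ (1 + .t || .id)"))
    fit2 <- suppressMessages(lme4::lmer(form2, data = d, REML = FALSE,
                                        control = ctrl))
    if (!lme4::isSingular(fit2, tol = 1e-4) &&
        as.numeric(stats::logLik(fit2)) >=
          as.numeric(stats::logLik(fit)) - 1e-4) {
      fit <- fit2
      diagonal <- TRUE
    }
  }
  k <- length(lme4::fixef(fit)) + length(lme4::getME(fit, "theta")) + 1L
  structure(list(model = fit, data = d,
                 logLik = as.numeric(stats::logLik(fit)),
                 n_obs = nrow(d), n_parameters = k,
                 time = time, time_center = ctr, quadratic = quadratic,
                 covariates = covariates, outcome = outcome,
                 diagonal_re = diagonal),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("Mixed model: %s ~ %s%s%s + (1 + time | participant), ML\n",
              x$outcome, x$time, if (x$quadratic) " + time^2" else "",
              if (length(x$covariates)) paste0(" + ",
                paste(x$covariates, collapse = " + ")) else ""))
  cat(sprintf("  n obs %d; logLik %.3f; k %d; time centred at %.3f\n",
              x$n_obs, x$logLik, x$n_parameters, x$time_center))
  if (x$diagonal_re) cat("  (random effects refit as independent after singular fit)\n")
  print(lme4::fixef(x$model))
  invisible(x)
}

#' @export
coef.lmm_fit <- function(object, ...) lme4::fixef(object$model)

#' @export
logLik.lmm_fit <- function(object, ...) stats::logLik(object$model)

#' Corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n - k - 1)` with `n` the number of
#' observations and `k` the number of estimated parameters (fixed effects
#' plus variance components for mixed models).
#'
#' @param object an `lmm_fit`, or a log-likelihood value.
#' @param k,n parameter and observation counts (for the default method).
#' @param ... unused.
#' @return numeric AICc.
#' @export
aicc <- function(object, ...) UseMethod("aicc")

#' @rdname aicc
#' @export
aicc.lmm_fit <- function(object, ...)
  aicc.default(object$logLik, object$n_parameters, object$n_obs)

#' @rdname aicc
#' @export
aicc.default <- function(object, k, n, ...) {
  ll <- as.numeric(object)
  if (n - k - 1 <= 0)
    stop("AICc undefined: need n > k + 1 (n = ", n, ", k = ", k, ")",
         call. = FALSE)
  -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Nakagawa marginal R-squared for a mixed model
#'
#' Proportion of outcome variance attributable to the fixed effects:
#' `var(fixed predictions) / (var(fixed) + mean random-effect variance +
#' residual variance)`. The random-effect contribution is the mean over
#' observations of the model-implied random-effect variance (Johnson's
#' random-slope extension).
#'
#' @param fit an `lmm_fit`.
#' @return numeric in \[0, 1\].
#' @export
marginal_r2 <- function(fit) {
  m <- fit$model
  X <- lme4::getME(m, "X")
  var_f <- stats::var(as.vector(X %*% lme4::fixef(m)))
  vc <- lme4::VarCorr(m)
  sig2 <- stats::sigma(m)^2
  # mean over observations of z_i' Sigma z_i, per random-effect grouping
  var_r <- 0
  d <- fit$data
  for (term in names(vc)) {
    S <- as.matrix(vc[[term]])
    z <- cbind(1, d$.t)[, seq_len(nrow(S)), drop = FALSE]
    var_r <- var_r + mean(rowSums((z %*% S) * z))
  }
  tot <- var_f + var_r + sig2
  if (tot <= 0) stop("marginal R2 undefined: zero total variance", call. = FALSE)
  min(max(var_f / tot, 0), 1)
}

#' Likelihood-ratio test of nested mixed models
#'
#' `chi^2 = 2 (logLik_full - logLik_nested)`, df = difference in parameter
#' counts, p from the chi-square distribution. Both fits must be ML fits on
#' identical observations, with the nested model's fixed effects a subset of
#' the full model's.
#'
#' @param nested,full `lmm_fit` objects.
#' @param tol tolerance for a slightly negative statistic from optimizer
#'   noise (clipped to 0 below it, an error beyond it). The default absorbs
#'   typical `lmer` optimizer termination error, which can leave the full
#'   model's log-likelihood a few 1e-3 below the nested one's when the extra
#'   parameter is null.
#' @return list `chisq`, `df`, `p_value`.
#' @export
lrt <- function(nested, full, tol = 0.01) {
  if (nested$n_obs != full$n_obs)
    stop("LRT requires identical observations in both fits", call. = FALSE)
  f_n <- names(lme4::fixef(nested$model))
  f_f <- names(lme4::fixef(full$model))
  if (!all(f_n %in% f_f) || nested$n_parameters > full$n_parameters)
    stop("models are not nested", call. = FALSE)
  stat <- 2 * (full$logLik - nested$logLik)
  if (stat < -tol)
    stop("negative likelihood-ratio statistic: the 'full' fit did not reach ",
         "the nested fit's likelihood (fitting problem)", call. = FALSE)
  stat <- max(stat, 0)
  df <- full$n_parameters - nested$n_parameters
  p <- if (df == 0) as.numeric(stat <= tol) else stats::pchisq(stat, df,
                                                               lower.tail = FALSE)
  list(chisq = stat, df = df, p_value = p)
}

#' Compare mixed models across time operationalizations
#'
#' Fits the same outcome model under each candidate time variable (age,
#' amyloid-positive time, p-tau217-positive time, ...) on identical
#' observation rows, and compares the fits with AICc, delta-AICc and
#' Nakagawa marginal R-squared. Candidate models use the same number of
#' predictors, so the AICc ranking reflects how well each clock explains
#' the outcome.
#'
#' @param data observation-level data frame.
#' @param outcome outcome column.
#' @param times named character vector of candidate time columns, e.g.
#'   `c(age = "age_years", amyloid_time = "t_amyloid", ptau_time = "t_ptau")`.
#' @param quadratic,covariates,id passed to [fit_lmm()].
#' @return object of class `model_comparison`: `table` (model, AICc,
#'   delta_AICc, marginal_R2, logLik, k, n), `fits` (named list of
#'   `lmm_fit`), `best`.
#' @export
compare_time_models <- function(data, outcome, times, quadratic = FALSE,
                                covariates = character(),
                                id = "participant_id") {
  stopifnot(length(times) >= 2, !is.null(names(times)))
  keep <- stats::complete.cases(data[c(outcome, unname(times), covariates, id)])
  d <- data[keep, ]
  fits <- lapply(times, function(tv)
    fit_lmm(d, outcome, tv, quadratic = quadratic, covariates = covariates,
            id = id))
  names(fits) <- names(times)
  ns <- vapply(fits, `[[`, numeric(1), "n_obs")
  if (length(unique(ns)) != 1)
    stop("candidate models were fit on unequal observation sets", call. = FALSE)
  aiccs <- vapply(fits, aicc, numeric(1))
  tab <- data.frame(model = names(times),
                    AICc = aiccs,
                    delta_AICc = aiccs - min(aiccs),
                    marginal_R2 = vapply(fits, marginal_r2, numeric(1)),
                    logLik = vapply(fits, `[[`, numeric(1), "logLik"),
                    k = vapply(fits, `[[`, numeric(1), "n_parameters"),
                    n = ns, row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, fits = fits,
                 best = tab$model[which.min(tab$AICc)]),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Time-operationalization model comparison (ML mixed models)\n")
  tab <- x$table
  tab$AICc <- round(tab$AICc, 1)
  tab$delta_AICc <- round(tab$delta_AICc, 1)
  tab$marginal_R2 <- round(tab$marginal_R2, 2)
  print(tab[c("model", "delta_AICc", "marginal_R2", "n")], row.names = FALSE)
  cat("best by AICc:", x$best, "\n")
  invisible(x)
}

#' Modelled decline rate at a given biomarker time
#'
#' For a quadratic-in-time mixed model, the instantaneous rate of change of
#' the fitted mean trajectory at time `t` (on the uncentred scale) is
#' `beta_lin + 2 beta_quad (t - centring constant)`; its standard error
#' follows from the fixed-effects covariance by the delta method (here the
#' rate is linear in the coefficients, so the delta method is exact).
#'
#' @param fit a quadratic `lmm_fit`.
#' @param t time in years on the original (uncentred) scale.
#' @return data frame `t, rate, se`.
#' @export
decline_rate_at <- function(fit, t) {
  if (!fit$quadratic)
    stop("decline_rate_at() requires a quadratic time term", call. = FALSE)
  b <- lme4::fixef(fit$model)
  V <- as.matrix(stats::vcov(fit$model))
  i1 <- which(names(b) == ".t"); i2 <- which(names(b) == "I(.t^2)")
  tc <- t - fit$time_center
  rate <- b[i1] + 2 * b[i2] * tc
  se <- vapply(tc, function(z) {
    g <- c(1, 2 * z)
    sqrt(drop(t(g) %*% V[c(i1, i2), c(i1, i2)] %*% g))
  }, numeric(1))
  data.frame(t = t, rate = as.numeric(rate), se = se)
}
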