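#' Group-based trajectory modelling (GBTM) of longitudinal biomarkers
#'
#' Fits a finite mixture of polynomial-in-age trajectory groups with shared
#' Gaussian residual variance by maximum likelihood (EM with multiple random
#' restarts). Group membership is at the participant level: a participant's
#' likelihood under a group is the product of Gaussian densities of all of
#' their observations around that group's polynomial mean trajectory. Ages
#' are mean-centred before fitting, so each group's intercept is its typical
#' level at the average observation age.
#'
#' @param data long-format observations for a single modality
#'   (`participant_id, age_years, value`); participants with fewer than two
#'   observations are dropped with a message.
#' @param n_groups number of trajectory groups (K).
#' @param order polynomial order of the group mean trajectories (1 = linear).
#' @param n_restarts number of random EM restarts.
#' @param max_iter,tol EM stopping rule: stop when the log-likelihood
#'   improves by less than `tol` or after `max_iter` iterations.
#' @param seed optional integer seed controlling the restarts.
#' @param sigma_floor lower bound for the residual SD (guards degenerate
#'   zero-variance solutions).
#'
#' @return an object of class `gbtm` with components `coefficients`
#'   (K x (order+1) matrix, groups ordered by ascending intercept), `se`
#'   (matching standard errors), `sigma` (shared residual SD), `pi` (mixing
#'   proportions), `posterior` (participants x K), `assignment` (named hard
#'   assignments), `logLik`, `BIC`, `n_participants`, `n_obs`, `age_center`,
#'   `loglik_trace` of the winning restart.
#'
#' @details The EM log-likelihood is asserted non-decreasing at every
#'   iteration. If a group collapses (posterior mass below one participant) a
#'   warning is raised and the model is refit with one group fewer. BIC uses
#'   the number of participants as the effective sample size.
#' @export
gbtm <- function(data, n_groups = 2, order = 1, n_restarts = 20,
                 max_iter = 500, tol = 1e-6, seed = NULL,
                 sigma_floor = 1e-6) {
  stopifnot(n_groups >= 1, order >= 0)
  if (!is.null(seed)) set.seed(seed)
  data <- data[order(data$participant_id, data$age_years), ]
  nobs <- table(data$participant_id)
  drop <- names(nobs)[nobs < 2]
  if (length(drop)) {
    message(length(drop), " participant(s) with < 2 observations excluded from GBTM")
    data <- data[!data$participant_id %in% drop, ]
  }
  if (!nrow(data)) stop("no participants with >= 2 observations", call. = FALSE)

  id <- factor(data$participant_id)
  ids <- levels(id)
  N <- length(ids)
  y <- data$value
  age_center <- mean(data$age_years)
  ac <- data$age_years - age_center
  X <- stats::poly(ac, degree = max(order, 1), raw = TRUE, simple = TRUE)
  X <- cbind(1, X[, seq_len(order), drop = FALSE])
  colnames(X) <- c("(Intercept)", if (order >= 1) paste0("age^", seq_len(order)))
  idx <- as.integer(id)

  # per-participant (mean, slope) summaries for k-means style initialization
  summ <- t(vapply(split(seq_along(y), idx), function(j) {
    if (length(j) >= 2) {
      fit <- stats::lm.fit(cbind(1, ac[j]), y[j])
      c(mean(y[j]), fit$coefficients[2])
    } else c(mean(y[j]), 0)
  }, numeric(2)))

  run_em <- function(post0) {
    ll_old <- -Inf
    trace <- numeric(0)
    post <- post0
    for (iter in seq_len(max_iter)) {
      # M-step
      pi_g <- pmax(colMeans(post), 1e-12)
      pi_g <- pi_g / sum(pi_g)
      B <- matrix(0, ncol(X), n_groups)
      w_obs <- post[idx, , drop = FALSE]
      for (g in seq_len(n_groups)) {
        w <- w_obs[, g]
        XtW <- t(X * w)
        B[, g] <- solve(XtW %*% X, XtW %*% y)
      }
      R <- y - X %*% B                      # n_obs x K residual matrix
      sigma2 <- sum(w_obs * R^2) / length(y)
      sigma <- max(sqrt(sigma2), sigma_floor)
      # E-step: participant-level log densities
      ld_obs <- stats::dnorm(R, sd = sigma, log = TRUE)
      ld <- rowsum(ld_obs, idx)             # N x K
      lp <- sweep(ld, 2, log(pi_g), `+`)
      m <- apply(lp, 1, max)
      ll <- sum(m + log(rowSums(exp(lp - m))))
      if (ll < ll_old - 1e-8)
        stop("internal error: EM log-likelihood decreased", call. = FALSE)
      trace <- c(trace, ll)
      post <- exp(lp - m - log(rowSums(exp(lp - m))))
      if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
      ll_old <- ll
    }
    list(logLik = ll, post = post, B = B, sigma = sigma, pi = pi_g,
         trace = trace, converged = iter < max_iter || abs(ll - ll_old) < tol)
  }

  init_posterior <- function(r) {
    if (n_groups == 1) return(matrix(1, N, 1))
    Z <- scale(summ)
    Z[!is.finite(Z)] <- 0
    cl <- tryCatch(
      stats::kmeans(Z, centers = n_groups, nstart = 1)$cluster,
      error = function(e) sample.int(n_groups, N, replace = TRUE))
    post <- matrix(0.1 / (n_groups - 1), N, n_groups)
    post[cbind(seq_len(N), cl)] <- 0.9
    # jitter so restarts differ
    post <- post * matrix(stats::runif(N * n_groups, 0.8, 1.2), N)
    post / rowSums(post)
  }

  best <- NULL
  for (r in seq_len(max(1L, n_restarts))) {
    fit <- tryCatch(run_em(init_posterior(r)), error = function(e) {
      if (grepl("log-likelihood decreased", conditionMessage(e))) stop(e)
      NULL
    })
    if (!is.null(fit) && (is.null(best) || fit$logLik > best$logLik)) best <- fit
  }
  if (is.null(best))
    stop("GBTM failed to converge in any restart", call. = FALSE)

  # degenerate class: effective mass below one participant
  mass <- colSums(best$post)
  if (any(mass < 1) && n_groups > 1) {
    warning(sprintf("GBTM group collapsed (mass %.2f); refitting with %d groups",
                    min(mass), n_groups - 1L))
    return(gbtm(data, n_groups - 1L, order, n_restarts, max_iter, tol, seed,
                sigma_floor))
  }

  # order groups by ascending intercept
  ord <- order(best$B[1, ])
  B <- best$B[, ord, drop = FALSE]
  post <- best$post[, ord, drop = FALSE]
  pi_g <- best$pi[ord]

  # coefficient SEs from the weighted information at the converged weights
  SE <- matrix(NA_real_, ncol(X), n_groups)
  w_obs <- post[idx, , drop = FALSE]
  for (g in seq_len(n_groups)) {
    XtWX <- t(X * w_obs[, g]) %*% X
    SE[, g] <- sqrt(diag(best$sigma^2 * solve(XtWX)))
  }

  n_par <- n_groups * ncol(X) + (n_groups - 1) + 1
  bic <- -2 * best$logLik + n_par * log(N)
  assignment <- max.col(post)
  names(assignment) <- ids
  rownames(post) <- ids

  structure(list(coefficients = t(B), se = t(SE), sigma = best$sigma,
                 pi = pi_g, posterior = post, assignment = assignment,
                 logLik = best$logLik, BIC = bic, n_parameters = n_par,
                 n_groups = n_groups, order = order,
                 n_participants = N, n_obs = length(y),
                 age_center = age_center, loglik_trace = best$trace,
                 converged = best$converged),
            class = "gbtm")
}

#' Select the number of GBTM groups by BIC
#'
#' Fits [gbtm()] for K in `k_range` and returns the fit with the lowest BIC.
#'
#' @inheritParams gbtm
#' @param k_range candidate group counts.
#' @return the selected `gbtm` fit, with a `bic_table` attribute.
#' @export
gbtm_select <- function(data, k_range = 1:4, order = 1, n_restarts = 20,
                        seed = NULL, ...) {
  fits <- lapply(k_range, function(k)
    tryCatch(suppressWarnings(
      gbtm(data, n_groups = k, order = order, n_restarts = n_restarts,
           seed = seed, ...)),
      error = function(e) NULL))
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("GBTM failed for all candidate K", call. = FALSE)
  bics <- vapply(fits[ok], `[[`, numeric(1), "BIC")
  best <- fits[ok][[which.min(bics)]]
  attr(best, "bic_table") <- data.frame(K = k_range[ok], BIC = bics)
  best
}

#' @export
print.gbtm <- function(x, ...) {
  cat(sprintf("GBTM fit: %d group(s), polynomial order %d\n", x$n_groups, x$order))
  cat(sprintf("  %d participants, %d observations; logLik %.3f, BIC %.3f\n",
              x$n_participants, x$n_obs, x$logLik, x$BIC))
  cat(sprintf("  residual SD %.4g (shared); ages centred at %.2f y\n",
              x$sigma, x$age_center))
  tab <- cbind(x$coefficients, pi = x$pi, n = as.vector(table(factor(x$assignment,
               levels = seq_len(x$n_groups)))))
  rownames(tab) <- paste0("group", seq_len(x$n_groups))
  print(round(tab, 4))
  invisible(x)
}

#' @export
summary.gbtm <- function(object, ...) {
  print(object)
  cat("\nIntercept standard errors:\n")
  print(round(object$se[, 1], 5))
  invisible(object)
}

#' @export
coef.gbtm <- function(object, ...) object$coefficients

#' @export
logLik.gbtm <- function(object, ...) {
  structure(object$logLik, df = object$n_parameters,
            nobs = object$n_participants, class = "logLik")
}
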