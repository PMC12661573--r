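# small longitudinal generator for mixed-model tests: y follows a quadratic
# in t with participant random intercepts/slopes and Gaussian noise
sim_lmm_data <- function(n_id = 40, n_vis = 4, b0 = 0, b1 = -0.1, b2 = 0,
                         ri_sd = 0.3, rs_sd = 0.05, sigma = 0.2, seed = 1,
                         t_start = NULL) {
  set.seed(seed)
  if (is.null(t_start)) t_start <- runif(n_id, -5, 10)
  ri <- rnorm(n_id, 0, ri_sd); rs <- rnorm(n_id, 0, rs_sd)
  rows <- lapply(seq_len(n_id), function(i) {
    t <- t_start[i] + seq(0, by = 2, length.out = n_vis)
    data.frame(participant_id = sprintf("p%03d", i), t = t,
               y = b0 + ri[i] + (b1 + rs[i]) * t + b2 * t^2 +
                 rnorm(n_vis, 0, sigma))
  })
  do.call(rbind, rows)
}

test_that("an exactly linear outcome is recovered with negligible residual", {
  d <- sim_lmm_data(n_id = 15, ri_sd = 0, rs_sd = 0, sigma = 0, seed = 2)
  fit <- fit_lmm(d, "y", "t")
  expect_equal(unname(coef(fit)[".t"]), -0.1, tolerance = 1e-6)
  expect_lt(stats::sigma(fit$model), 1e-3)
})

test_that("random-intercept-only data yields a near-zero slope variance", {
  d <- sim_lmm_data(n_id = 60, n_vis = 5, ri_sd = 0.5, rs_sd = 0, sigma = 0.1,
                    seed = 3)
  fit <- fit_lmm(d, "y", "t")
  vc <- as.data.frame(lme4::VarCorr(fit$model))
  slope_sd <- vc$sdcor[which(vc$var1 == ".t" & is.na(vc$var2) &
                               vc$grp != "Residual")]
  expect_lt(max(slope_sd), 0.05)
})

test_that("AICc matches its closed form and approaches AIC for large n", {
  expect_equal(aicc(-100, k = 5, n = 50), 210 + 60 / 44, tolerance = 1e-12)
  expect_equal(aicc(-100, k = 5, n = 1e7), 210, tolerance = 1e-4)
  expect_error(aicc(-100, k = 5, n = 6), "n > k")
  d <- sim_lmm_data(seed = 4)
  fit <- fit_lmm(d, "y", "t")
  # recompute from the stored components
  expect_equal(aicc(fit),
               -2 * fit$logLik + 2 * fit$n_parameters +
                 2 * fit$n_parameters * (fit$n_parameters + 1) /
                 (fit$n_obs - fit$n_parameters - 1),
               tolerance = 1e-12)
})

test_that("marginal R2 is bounded and tracks a known variance partition", {
  # var(fixed) = b1^2 var(t); choose components for a fixed share of 0.35
  d <- sim_lmm_data(n_id = 80, n_vis = 5, b1 = -0.2, ri_sd = sqrt(0.06),
                    rs_sd = 0, sigma = sqrt(0.05), seed = 5)
  fit <- fit_lmm(d, "y", "t")
  r2 <- marginal_r2(fit)
  var_f <- 0.04 * var(d$t)
  expect_equal(r2, var_f / (var_f + 0.06 + 0.05), tolerance = 0.06)
  expect_gte(r2, 0); expect_lte(r2, 1)
})

test_that("likelihood-ratio tests follow the chi-square closed form", {
  d <- sim_lmm_data(n_id = 40, seed = 6)
  d$junk <- rnorm(nrow(d))
  nested <- fit_lmm(d, "y", "t")
  full <- fit_lmm(d, "y", "t", covariates = "junk")
  res <- lrt(nested, full)
  expect_equal(res$chisq, 2 * (full$logLik - nested$logLik), tolerance = 1e-9)
  expect_equal(res$df, 1L)
  # independent oracle: chi-square df 1 tail via the normal distribution
  expect_equal(res$p_value, 2 * pnorm(sqrt(res$chisq), lower.tail = FALSE),
               tolerance = 1e-9)
  # identical models: zero statistic, p = 1
  same <- lrt(nested, nested)
  expect_equal(same$chisq, 0)
  expect_equal(same$p_value, 1)
  expect_error(lrt(full, nested), "not nested")
})

test_that("model comparison is degenerate-safe and flags the generative clock", {
  d <- sim_lmm_data(n_id = 50, n_vis = 4, b1 = -0.15, seed = 7)
  d$t_copy1 <- d$t; d$t_copy2 <- d$t
  cmp <- compare_time_models(d, "y", c(a = "t", b = "t_copy1", c = "t_copy2"))
  expect_lt(diff(range(cmp$table$AICc)), 1e-6)
  expect_gte(sum(cmp$table$delta_AICc == 0), 1L)

  # outcome driven by t; a noisy shifted clock and a diluted clock compete
  set.seed(8)
  per_id_shift <- rnorm(50, 0, 6)
  d$t_shifted <- d$t + per_id_shift[as.integer(factor(d$participant_id))]
  cmp2 <- compare_time_models(d, "y", c(true_clock = "t", shifted = "t_shifted"))
  expect_equal(cmp2$best, "true_clock")
  expect_equal(sum(cmp2$table$delta_AICc == 0), 1L)
  expect_true(all(cmp2$table$marginal_R2 >= 0 & cmp2$table$marginal_R2 <= 1))
})

test_that("decline rates are the analytic derivative of the fitted curve", {
  d <- sim_lmm_data(n_id = 60, n_vis = 5, b1 = -0.1, b2 = -0.008, sigma = 0.15,
                    seed = 9, t_start = runif(60, 0, 10))
  fit <- fit_lmm(d, "y", "t", quadratic = TRUE)
  rr <- decline_rate_at(fit, c(5, 10))
  b <- coef(fit)
  # closed form on the centred scale
  expect_equal(rr$rate,
               unname(b[".t"] + 2 * b["I(.t^2)"] * (c(5, 10) - fit$time_center)),
               tolerance = 1e-12)
  # finite-difference check against the fitted mean curve
  h <- 1e-5
  mean_at <- function(t) {
    tc <- t - fit$time_center
    unname(b["(Intercept)"] + b[".t"] * tc + b["I(.t^2)"] * tc^2)
  }
  fd <- (mean_at(5 + h) - mean_at(5 - h)) / (2 * h)
  expect_equal(rr$rate[1], fd, tolerance = 1e-6)
  # rate at the centring constant is the linear coefficient itself
  r0 <- decline_rate_at(fit, fit$time_center)
  expect_equal(r0$rate, unname(b[".t"]), tolerance = 1e-12)
  expect_error(decline_rate_at(fit_lmm(d, "y", "t"), 5), "quadratic")
})

test_that("quadratic fixed effects are recovered within two standard errors", {
  d <- sim_lmm_data(n_id = 60, n_vis = 5, b1 = -0.1, b2 = -0.008,
                    ri_sd = 0.3, rs_sd = 0.02, sigma = 0.15, seed = 10,
                    t_start = runif(60, -2, 12))
  fit <- fit_lmm(d, "y", "t", quadratic = TRUE)
  b <- coef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit$model))))
  names(se) <- names(b)
  # generative coefficients on the centred scale
  ctr <- fit$time_center
  b1c <- -0.1 + 2 * (-0.008) * ctr
  expect_lt(abs(b[".t"] - b1c) / se[".t"], 2.5)
  expect_lt(abs(b["I(.t^2)"] - (-0.008)) / se["I(.t^2)"], 2.5)
})
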