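test_that("rate-of-flow factor reproduces the worked examples", {
  # subject with intercept deviation -3.850 and slope deviation 0.081 at
  # 6.72 months flows 2.368 times faster than the population average
  expect_equal(round(rate_scaling_factor(list(b0 = -3.850, b1 = 0.081),
                                         t = 6.72, alpha = c(0.246, 0.156)), 3),
               2.368)
  # one-unit intercept increase: factor exp(-0.246), printed as 0.781
  expect_lt(abs(rate_scaling_factor(list(b0 = 1, b1 = 0),
                                    t = 3, alpha = c(0.246, 0.156)) - 0.781),
            1e-3)
  # one-unit slope increase per month: factor exp(-0.156), printed 0.856
  expect_lt(abs(rate_scaling_factor(list(b0 = 0, b1 = 1),
                                    t = 1, alpha = c(0.246, 0.156)) - 0.856),
            1e-3)
  # baseline subject: factor 1 at any time and any coefficients
  expect_equal(rate_scaling_factor(list(b0 = 0, b1 = 0), t = c(0, 5, 50),
                                   alpha = c(1.7, -2.2)), rep(1, 3))
})

test_that("regression likelihood reduces to the plain likelihood at alpha = 0", {
  p <- coxian_params(c(0.4, 0), c(0.1, 0.7))
  d <- surv_df(c(2, 5, 9, 14, 30), event = c(1, 1, 0, 1, 0))
  eff <- tibble::tibble(id = d$id, b0 = rnorm(5), b1 = rnorm(5, 0, 0.1))
  expect_equal(coxian_regression_loglik(p, c(0, 0), d, eff),
               coxian_loglik(p, d))
})

test_that("regression likelihood equals per-subject scaled matrix densities", {
  p <- coxian_params(c(0.4, 0), c(0.1, 0.7))
  alpha <- c(0.3, 0.12)
  d <- surv_df(c(4.0, 11.0, 22.0), event = c(1, 1, 0))
  eff <- tibble::tibble(id = d$id, b0 = c(-1.2, 0.4, 2.0),
                        b1 = c(0.05, -0.08, 0.01))
  ll <- 0
  for (i in 1:3) {
    cf <- exp(-eff$b0[i] * alpha[1] - eff$b1[i] * d$time[i] * alpha[2])
    ps <- scaled_parameters(p, cf)
    ll <- ll + if (d$event[i] == 1) {
      log(coxian_pdf(ps, d$time[i], method = "matrix"))
    } else {
      log(coxian_survivor(ps, d$time[i], method = "matrix"))
    }
  }
  expect_equal(coxian_regression_loglik(p, alpha, d, eff), ll,
               tolerance = 1e-10)
})

test_that("coefficients are orthogonal to absent covariate variation", {
  p <- coxian_params(c(0.4, 0), c(0.1, 0.7))
  d <- surv_df(c(3, 8, 19), event = 1)
  eff0 <- tibble::tibble(id = d$id, b0 = 0, b1 = c(0.1, -0.2, 0.05))
  expect_equal(coxian_regression_loglik(p, c(0.4, 0.1), d, eff0),
               coxian_regression_loglik(p, c(0.8, 0.1), d, eff0))
})

test_that("a missing effects record raises a keyed error", {
  p <- coxian_params(0, 0.5)
  d <- surv_df(c(1, 2), id = c("a", "b"))
  eff <- tibble::tibble(id = "a", b0 = 0.1, b1 = 0)
  expect_error(coxian_regression_loglik(p, c(0.1, 0.1), d, eff),
               "subject 'b'", class = "coxianjm_missing_effects")
})

test_that("a time-fixed factor acts as a time change on individual curves", {
  base <- renal_params()
  fitlike <- list(params = base, alpha = c(0.246, 0.156))
  eff <- tibble::tibble(id = "s1", b0 = -2.0, b1 = 0)  # constant factor
  cf <- rate_scaling_factor(eff, 0, c(0.246, 0.156))
  tg <- c(0, 2, 7, 18, 40)
  cur <- individual_curves(fitlike, eff, tg)
  expect_equal(cur$survivor, coxian_survivor(base, cf * tg), tolerance = 1e-12)
  expect_equal(cur$hazard, cf * coxian_hazard(base, cf * tg), tolerance = 1e-12)
  expect_equal(cur$factor, rep(cf, length(tg)))
  # baseline subject reproduces the population-average curves
  eff0 <- tibble::tibble(id = "s0", b0 = 0, b1 = 0)
  cur0 <- individual_curves(fitlike, eff0, tg)
  expect_equal(cur0$survivor, coxian_survivor(base, tg))
  expect_equal(cur0$hazard, coxian_hazard(base, tg))
})

test_that("the worked-example subject's hazard approaches the scaled final rate", {
  fitlike <- list(params = renal_params(), alpha = c(0.246, 0.156))
  eff <- tibble::tibble(id = "143", b0 = -3.850, b1 = 0)
  # a time-fixed factor of 2.368 scales the limiting hazard to 0.142
  eff$b0 <- -log(2.368) / 0.246
  # the tied slow phases make the approach O(1/t); evaluate deep in the tail
  cur <- individual_curves(fitlike, eff, c(2000, 4000))
  expect_equal(round(cur$hazard, 3), c(0.142, 0.142))
  expect_true(all(abs(cur$hazard - 2.368 * 0.06) < 1e-3))
})

test_that("normal CIs reproduce the printed bootstrap intervals", {
  ci1 <- normal_ci(exp(-0.246), 0.0613)
  expect_lt(max(abs(c(ci1$conf_low, ci1$conf_high) - c(0.662, 0.902))), 1e-3)
  ci2 <- normal_ci(exp(-0.156), 0.0463)
  expect_lt(max(abs(c(ci2$conf_low, ci2$conf_high) - c(0.764, 0.946))), 1.1e-3)
  # interval arithmetic is exactly estimate +/- 1.96 se
  expect_identical(ci1$conf_low, exp(-0.246) - 1.96 * 0.0613)
  expect_identical(ci1$conf_high, exp(-0.246) + 1.96 * 0.0613)
})

test_that("significance is read off the interval with a closed-interval rule", {
  df <- tibble::tibble(term = c("a", "b", "c"),
                       conf_low = c(0.662, 0.9, 1.0),
                       conf_high = c(0.902, 1.1, 1.2))
  sig <- significance_from_ci(df)
  expect_equal(sig$significant, c(TRUE, FALSE, FALSE))
})

test_that("regression fits recover the generating coefficients", {
  cfg <- cohort_config(n_subjects = 800, alpha = c(0.25, 0.15), seed = 1003)
  coh <- generate_cohort(cfg)
  fit <- fit_coxian_regression(coh$survival, coh$effects, 3,
                               n_restarts = 5, seed = 303)
  expect_true(fit$alpha[1] > 0 && fit$alpha[2] > 0)
  expect_lt(abs(fit$alpha[1] - 0.25), 0.15)
  expect_lt(abs(fit$alpha[2] - 0.15), 0.12)
  expect_equal(fit$aic, -2 * fit$loglik + 2 * (2 * 3 - 1 + 2))
  # determinism
  fit2 <- fit_coxian_regression(coh$survival, coh$effects, 3,
                                n_restarts = 5, seed = 303)
  expect_identical(fit$alpha, fit2$alpha)
  expect_identical(fit$params, fit2$params)
})

test_that("with all effects zero the regression degenerates to the plain fit", {
  sim <- sample_absorption_times(coxian_params(c(0.3, 0), c(0.05, 0.6)),
                                 800, seed = 17)
  d <- surv_df(sim$time)
  eff0 <- tibble::tibble(id = d$id, b0 = 0, b1 = 0)
  plain <- fit_coxian(d, 2, n_restarts = 8, seed = 19)
  reg <- fit_coxian_regression(d, eff0, 2, n_restarts = 8, seed = 19)
  expect_equal(reg$loglik, plain$loglik, tolerance = 1e-5)
  expect_equal(c(reg$params$lambda, reg$params$mu),
               c(plain$params$lambda, plain$params$mu), tolerance = 0.02)
})

test_that("bootstrap summaries recompute their intervals and degenerate to zero spread", {
  # degenerate resample universe: every subject identical, so every
  # replicate refit sees the same data and the factor SE is zero
  d <- surv_df(rep(6, 15), event = 1)
  eff <- tibble::tibble(id = d$id, b0 = 0.5, b1 = 0.02)
  fit <- fit_coxian_regression(d, eff, 1, n_restarts = 3, seed = 23)
  boot <- bootstrap_coxian(fit, B = 4, seed = 29)
  expect_equal(boot$summary$se, c(0, 0))
  expect_equal(boot$summary$conf_low, boot$summary$estimate)
  # interval arithmetic is reproduced bit-for-bit from the stored SEs
  expect_identical(boot$summary$conf_low,
                   boot$summary$estimate - 1.96 * boot$summary$se)
  expect_identical(boot$summary$conf_high,
                   boot$summary$estimate + 1.96 * boot$summary$se)
})
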