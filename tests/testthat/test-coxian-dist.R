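test_that("single-phase quantities match the exponential closed forms", {
  p <- coxian_params(0, 0.5)
  expect_equal(coxian_pdf(p, 0), 0.5)
  expect_equal(coxian_pdf(p, 2), 0.5 * exp(-1))
  expect_equal(coxian_pdf(p, 2, "analytic"), 0.5 * exp(-1))
  expect_equal(coxian_survivor(p, 0), 1)
  expect_equal(coxian_survivor(p, 2), exp(-1))
  expect_equal(coxian_hazard(p, c(0, 1, 7, 30)), rep(0.5, 4))
  expect_equal(coxian_cum_hazard(p, 4), 2.0)
  expect_equal(coxian_cum_hazard(p, 0), 0)
  expect_error(coxian_pdf(p, -1), "non-negative")
  expect_error(coxian_survivor(p, -0.5), "non-negative")
})

test_that("analytic expansion matches a hand-derived two-phase density", {
  # lambda = (1, 0), mu = (0.5, 2): pi = (1/3, 2/3), C12 = 4, C22 = -3,
  # so f(t) = 4.5 e^{-1.5 t} - 4 e^{-2 t} (integrates to 3 - 2 = 1)
  p <- coxian_params(c(1, 0), c(0.5, 2))
  tg <- seq(0, 6, by = 0.3)
  expect_equal(coxian_pdf(p, tg, "analytic"), 4.5 * exp(-1.5 * tg) - 4 * exp(-2 * tg),
               tolerance = 1e-12)
})

test_that("analytic and matrix-exponential routes agree to 1e-10 relative", {
  for (p in param_battery(20)) {
    tg <- seq(0.05, 30, length.out = 20)
    fa <- coxian_pdf(p, tg, "analytic")
    fm <- coxian_pdf(p, tg, "matrix")
    expect_lt(max(abs(fa - fm) / pmax(fm, 1e-12)), 1e-10)
    sa <- coxian_survivor(p, tg, "analytic")
    sm <- coxian_survivor(p, tg, "matrix")
    expect_lt(max(abs(sa - sm) / pmax(sm, 1e-12)), 1e-10)
  }
})

test_that("near-tied total rates are flagged and routed robustly", {
  p <- renal_params()  # total rates 0.0600000000902 vs 0.060: degenerate
  expect_error(coxian_pdf(p, 1, "analytic"), class = "coxianjm_degenerate")
  tg <- c(0, 0.5, 3, 12, 24, 60, 120)
  expect_equal(coxian_pdf(p, tg), coxian_pdf(p, tg, "matrix"), tolerance = 1e-10)
  expect_equal(coxian_survivor(p, tg), coxian_survivor(p, tg, "matrix"),
               tolerance = 1e-10)
})

test_that("densities integrate to one", {
  for (p in param_battery(8, seed = 3)) {
    total <- integrate(function(x) coxian_pdf(p, x), 0, Inf,
                       rel.tol = 1e-9)$value
    expect_equal(total, 1, tolerance = 1e-6)
  }
})

test_that("survivor is one minus the integrated density", {
  p <- renal_params()
  S24 <- coxian_survivor(p, 24)
  cdf24 <- integrate(function(x) coxian_pdf(p, x, "matrix"), 0, 24,
                     rel.tol = 1e-10)$value
  expect_equal(S24, 1 - cdf24, tolerance = 1e-8)
  grid <- c(2, 10, 50)
  for (tt in grid) {
    expect_equal(coxian_survivor(p, tt),
                 1 - integrate(function(x) coxian_pdf(p, x), 0, tt,
                               rel.tol = 1e-10)$value,
                 tolerance = 1e-8)
  }
})

test_that("hazard equals density over survivor and converges to mu_n", {
  p2 <- coxian_params(c(1, 0), c(0.2, 2))
  tg <- seq(0.2, 8, length.out = 10)
  expect_equal(coxian_hazard(p2, tg),
               coxian_pdf(p2, tg) / coxian_survivor(p2, tg), tolerance = 1e-12)
  r <- renal_params()
  h <- coxian_hazard(r, c(50, 100, 200, 400, 800))
  expect_true(all(diff(abs(h - 0.06)) < 0)) # monotone approach to the limit
  expect_lt(abs(coxian_hazard(r, 200) - 0.06), 0.005)
  expect_lt(abs(coxian_hazard(r, 1500) - 0.06), 1e-3)
  # hazard bounded by the range of absorption rates
  for (p in param_battery(6, seed = 9)) {
    hz <- coxian_hazard(p, seq(0.1, 40, length.out = 25))
    expect_true(all(hz >= min(p$mu) - 1e-9 & hz <= max(p$mu) + 1e-9))
  }
})

test_that("cumulative hazard matches quadrature of the hazard", {
  p <- renal_params()
  for (tt in c(5, 20, 60)) {
    expect_equal(coxian_cum_hazard(p, tt),
                 integrate(function(x) coxian_hazard(p, x), 0, tt,
                           rel.tol = 1e-10)$value,
                 tolerance = 1e-6)
  }
  tg <- seq(0, 100, by = 5)
  H <- coxian_cum_hazard(p, tg)
  expect_equal(H[1], 0)
  expect_true(all(diff(H) > 0))
})

test_that("absorption probabilities match the worked example and sum to one", {
  pis <- absorption_probabilities(renal_params())$prob
  expect_equal(signif(pis[1], 3), 1.50e-9)
  expect_equal(round(pis[2], 3), 0.482)
  expect_equal(round(pis[3], 3), 0.518)
  expect_equal(sum(pis), 1, tolerance = 1e-12)
  expect_equal(absorption_probabilities(coxian_params(0, 0.7))$prob, 1)
  for (p in param_battery(10, seed = 5)) {
    expect_equal(sum(absorption_probabilities(p)$prob), 1, tolerance = 1e-12)
  }
})

test_that("exit-phase frequencies of simulated trajectories match pi", {
  set.seed(11)
  p <- coxian_params(c(0.8, 0.3, 0.9, 0), c(0.1, 0.4, 0.2, 0.7))
  m <- 200000
  sim <- sample_absorption_times(p, m, seed = 12)
  pis <- absorption_probabilities(p)$prob
  emp <- tabulate(sim$phase, nbins = 4) / m
  se <- sqrt(pis * (1 - pis) / m)
  expect_true(all(abs(emp - pis) <= 3 * se))
})

test_that("phase partition reproduces the 278/577 split and the floor rule", {
  r <- renal_params()
  part <- phase_time_bounds(seq_len(577), absorption_probabilities(r))
  expect_equal(part$bounds$size, c(0, 278, 299))
  expect_equal(part$bounds$lower, c(0, 0, 278))
  expect_equal(part$bounds$upper, c(0, 278, 577))
  # single phase: everything in phase 1
  p1 <- phase_time_bounds(c(4, 1, 9), c(1))
  expect_equal(p1$assignments$phase, rep(1L, 3))
  expect_equal(p1$assignments$time, c(1, 4, 9))
  # floor-then-remainder-to-last: pi = (0.5, 0.5), M = 5 -> blocks 2 and 3
  p5 <- phase_time_bounds(seq_len(5), c(0.5, 0.5))
  expect_equal(p5$bounds$size, c(2L, 3L))
  expect_error(phase_time_bounds(numeric(0), c(1)), "at least one")
  expect_error(phase_time_bounds(1:3, c(0.4, 0.4)), "sum to 1")
})

test_that("sampling is reproducible and matches closed-form moments", {
  s1 <- sample_absorption_times(renal_params(), 500, seed = 99)
  s2 <- sample_absorption_times(renal_params(), 500, seed = 99)
  expect_identical(s1, s2)
  exp_samp <- sample_absorption_times(coxian_params(0, 0.5), 100000, seed = 4)
  se <- 2 / sqrt(100000)  # exponential(0.5): mean 2, sd 2
  expect_lt(abs(mean(exp_samp$time) - 2), 3 * se)
})

test_that("empirical survivor of simulated times tracks the model survivor", {
  p <- renal_params()
  m <- 100000
  sim <- sample_absorption_times(p, m, seed = 21)
  for (tt in c(6, 12, 24)) {
    S <- coxian_survivor(p, tt)
    emp <- mean(sim$time > tt)
    expect_lt(abs(emp - S), 3 * sqrt(S * (1 - S) / m))
  }
})

test_that("per-trajectory scaling factors act as a time change in sampling", {
  p <- coxian_params(c(0.4, 0), c(0.1, 0.6))
  fast <- sample_absorption_times(p, 50000, seed = 31, factor = 2)
  base <- sample_absorption_times(p, 50000, seed = 32)
  # scaling all rates by 2 halves the time scale
  expect_lt(abs(mean(fast$time) - mean(base$time) / 2),
            3 * sd(base$time) / sqrt(50000))
})
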