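#' Configuration of a synthetic joint longitudinal-survival cohort
#'
#' Bundles the true parameter values from which [generate_cohort()]
#' simulates: the longitudinal layer (fixed effects, random-effect
#' covariance, residual variance), the survival layer (baseline Coxian
#' rates and covariate coefficients), the visit schedule and the
#' administrative censoring time.
#'
#' @param n_subjects Number of subjects.
#' @param visit_mean,visit_min,visit_max Per-subject visit counts are drawn
#'   from a shifted negative binomial with this mean, truncated to the
#'   given range; visits are monthly starting at time 0.
#' @param visit_size Negative-binomial size (dispersion) parameter.
#' @param beta Named fixed effects: `intercept`, `time`, `x1` (continuous
#'   covariate), `x2` (binary covariate), on the response scale (g/dL for
#'   an Hb-like biomarker).
#' @param D True 2x2 random-effect covariance (intercept, slope).
#' @param sigma2 Residual variance.
#' @param baseline True baseline [coxian_params()].
#' @param alpha True covariate coefficients `(alpha1, alpha2)` scaling the
#'   rates by `exp(-b0 alpha1 - b1 t alpha2)`.
#' @param censoring_time Administrative cutoff in months.
#' @param grid_step Step (months) of the piecewise-constant approximation
#'   used when the scaling factor is genuinely time-varying.
#' @param seed Integer seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 577,
                          visit_mean = 18, visit_min = 2, visit_max = 84,
                          visit_size = 4,
                          beta = c(intercept = 10.5, time = -0.05,
                                   x1 = 0.02, x2 = 0.3),
                          D = matrix(c(1.5, -0.181, -0.181, 0.04), 2, 2),
                          sigma2 = 1.0,
                          baseline = coxian_params(c(0.060, 0.467, 0),
                                                   c(9.02e-11, 0.435, 0.060)),
                          alpha = c(0.246, 0.156),
                          censoring_time = 120,
                          grid_step = 0.1,
                          seed = 1) {
  stopifnot(n_subjects >= 1, censoring_time > 0, grid_step > 0,
            inherits(baseline, "coxian_params"), length(alpha) == 2)
  D <- as.matrix(D)
  ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-10)) abort("`D` must be positive semi-definite.")
  if (sigma2 <= 0) abort("`sigma2` must be positive.")
  structure(
    list(n_subjects = as.integer(n_subjects), visit_mean = visit_mean,
         visit_min = as.integer(visit_min), visit_max = as.integer(visit_max),
         visit_size = visit_size, beta = beta, D = D, sigma2 = sigma2,
         baseline = baseline, alpha = alpha, censoring_time = censoring_time,
         grid_step = grid_step, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Preset emulating a haemodialysis registry cohort
#'
#' 577 subjects with on average 18 monthly haemoglobin measurements each
#' (range 2-84), a negatively correlated random intercept and slope, and
#' absorption times from a three-phase Coxian with baseline rates
#' `lambda = (0.060, 0.467, 0)`, `mu = (9.02e-11, 0.435, 0.060)` scaled by
#' `exp(-0.246 b0 - 0.156 b1 t)`. The longitudinal-layer values (fixed
#' effects, `D`, `sigma2`) are synthetic stand-ins on an Hb-like scale.
#'
#' @param seed Integer seed.
#' @return A [cohort_config()].
#' @export
ckd_preset <- function(seed = 1) cohort_config(seed = seed)

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("<cohort_config: %d subjects, alpha = (%.3f, %.3f), seed %d>\n",
              x$n_subjects, x$alpha[1], x$alpha[2], x$seed))
  invisible(x)
}

# Absorption under a time-varying rate-of-flow factor, approximated as
# piecewise constant on a grid of width dt; within a step the embedded
# competing-risk chain is simulated exactly (multiple transitions allowed).
simulate_timevarying_absorption <- function(params, alpha, b, dt, horizon) {
  n <- nrow(b)
  lam <- params$lambda
  mu <- params$mu
  p_absorb <- mu / (lam + mu)
  done <- logical(n)
  phase <- rep(1L, n)
  abs_time <- rep(NA_real_, n)
  n_steps <- ceiling(horizon / dt)
  for (s in seq_len(n_steps)) {
    act <- which(!done)
    if (!length(act)) break
    t0 <- (s - 1) * dt
    cfac <- exp(-b[act, 1] * alpha[1] - b[act, 2] * t0 * alpha[2])
    rem <- rep(dt, length(act))
    idx <- seq_along(act)
    while (length(idx)) {
      subj <- act[idx]
      ph <- phase[subj]
      dwell <- rexp(length(idx), cfac[idx] * (lam[ph] + mu[ph]))
      tr <- dwell < rem[idx]
      if (!any(tr)) break
      j <- idx[tr]
      sj <- act[j]
      rem[j] <- rem[j] - dwell[tr]
      absorb <- runif(length(sj)) < p_absorb[phase[sj]]
      ab <- sj[absorb]
      done[ab] <- TRUE
      abs_time[ab] <- t0 + (dt - rem[j][absorb])
      move <- sj[!absorb]
      phase[move] <- phase[move] + 1L
      idx <- j[!absorb]
    }
  }
  list(time = abs_time, absorbed = done)
}

#' Generate a synthetic joint cohort
#'
#' Simulates, per subject: random effects `b_i ~ N(0, D)`; a continuous
#' covariate `x1` (age-like, N(54, 12^2)) and binary `x2` (Bernoulli 0.5);
#' an absorption time from the baseline Coxian with rates scaled by
#' `exp(-b0 alpha1 - b1 t alpha2)` (exact phase-wise sampling when the
#' factor is time-constant, a piecewise-constant grid approximation
#' otherwise); monthly biomarker responses
#' `y = X beta + b0 + b1 t + eps`, `eps ~ N(0, sigma2)`. Times beyond the
#' censoring cutoff are administratively censored, and longitudinal
#' records after the event time are dropped — deliberately reproducing the
#' informative-dropout regime of registry data.
#'
#' @param config A [cohort_config()].
#' @return A list of class `cohort_data` with tibbles `longitudinal`
#'   (`id`, `time`, `response`, `x1`, `x2`), `survival` (`id`, `time`,
#'   `event`), `effects` (true `id`, `b0`, `b1`), and the `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  ids <- sprintf("s%04d", seq_len(n))
  b <- MASS::mvrnorm(n, mu = c(0, 0), Sigma = config$D)
  b <- matrix(b, ncol = 2)
  x1 <- rnorm(n, 54, 12)
  x2 <- rbinom(n, 1, 0.5)
  alpha <- config$alpha

  time_varying <- alpha[2] != 0 && config$D[2, 2] > 0
  if (time_varying) {
    sim <- simulate_timevarying_absorption(config$baseline, alpha, b,
                                           config$grid_step, config$censoring_time)
    surv_time <- ifelse(sim$absorbed, sim$time, config$censoring_time)
    event <- as.integer(sim$absorbed)
  } else {
    cfac <- exp(-b[, 1] * alpha[1])
    draws <- sample_absorption_times(config$baseline, n, factor = cfac)
    surv_time <- pmin(draws$time, config$censoring_time)
    event <- as.integer(draws$time <= config$censoring_time)
  }
  surv_time <- pmax(surv_time, 1e-8)  # guard exact zeros

  m <- config$visit_min +
    rnbinom(n, size = config$visit_size,
            mu = max(config$visit_mean - config$visit_min, 0.1))
  m <- pmin(m, config$visit_max)
  long <- tibble(
    id = rep(ids, m),
    time = unlist(lapply(m, function(k) seq(0, k - 1))),
    x1 = rep(x1, m),
    x2 = rep(x2, m),
    b0 = rep(b[, 1], m),
    b1 = rep(b[, 2], m),
    surv = rep(surv_time, m)
  )
  long <- filter(long, .data$time <= .data$surv)
  long$response <- config$beta["intercept"] +
    config$beta["time"] * long$time +
    config$beta["x1"] * long$x1 +
    config$beta["x2"] * long$x2 +
    long$b0 + long$b1 * long$time +
    rnorm(nrow(long), 0, sqrt(config$sigma2))
  long <- select(long, all_of(c("id", "time", "response", "x1", "x2")))

  structure(
    list(longitudinal = long,
         survival = tibble(id = ids, time = surv_time, event = event),
         effects = tibble(id = ids, b0 = b[, 1], b1 = b[, 2]),
         config = config),
    class = "cohort_data"
  )
}

#' @export
print.cohort_data <- function(x, ...) {
  cat(sprintf("<cohort_data: %d subjects, %d longitudinal records, %d events>\n",
              nrow(x$survival), nrow(x$longitudinal), sum(x$survival$event)))
  invisible(x)
}

#' Serialise a cohort configuration to flat key-value JSON
#'
#' @param config A [cohort_config()].
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  flat <- c(
    list(n_subjects = config$n_subjects, visit_mean = config$visit_mean,
         visit_min = config$visit_min, visit_max = config$visit_max,
         visit_size = config$visit_size,
         beta_intercept = unname(config$beta["intercept"]),
         beta_time = unname(config$beta["time"]),
         beta_x1 = unname(config$beta["x1"]),
         beta_x2 = unname(config$beta["x2"]),
         d11 = config$D[1, 1], d12 = config$D[1, 2], d22 = config$D[2, 2],
         sigma2 = config$sigma2,
         alpha1 = config$alpha[1], alpha2 = config$alpha[2],
         censoring_time = config$censoring_time,
         grid_step = config$grid_step, seed = config$seed),
    coxian_params_to_config(config$baseline)
  )
  jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a cohort configuration from flat key-value JSON
#'
#' @param path File written by [write_cohort_config()].
#' @return A [cohort_config()].
#' @export
read_cohort_config <- function(path) {
  x <- jsonlite::read_json(path)
  cohort_config(
    n_subjects = x$n_subjects, visit_mean = x$visit_mean,
    visit_min = x$visit_min, visit_max = x$visit_max,
    visit_size = x$visit_size,
    beta = c(intercept = x$beta_intercept, time = x$beta_time,
             x1 = x$beta_x1, x2 = x$beta_x2),
    D = matrix(c(x$d11, x$d12, x$d12, x$d22), 2, 2),
    sigma2 = x$sigma2,
    baseline = coxian_params_from_config(x),
    alpha = c(x$alpha1, x$alpha2),
    censoring_time = x$censoring_time,
    grid_step = x$grid_step,
    seed = x$seed
  )
}
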