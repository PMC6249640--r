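#' Coxian phase-type distribution functions
#'
#' Density, survivor, hazard and cumulative hazard of the Coxian phase-type
#' distribution. Two density routes are implemented: the defining
#' matrix-exponential form `f(t) = p exp(Qt) q`, and an analytic expansion
#' as a signed mixture of exponentials,
#' `f(t) = sum_h pi_h sum_{k<=h} C_kh (lambda_k + mu_k) exp(-(lambda_k+mu_k) t)`,
#' which is much faster but undefined when two phases share the same total
#' exit rate. `method = "auto"` (the default) uses the analytic expansion
#' when the total rates are well separated and falls back to the matrix
#' exponential otherwise; ties are detected at a relative tolerance of
#' 1e-9 on the largest total rate, because the expansion's denominators
#' amplify rounding error without bound as rates coalesce.
#'
#' @param params A [coxian_params()] object.
#' @param t Vector of non-negative times (months).
#' @param method One of `"auto"`, `"analytic"`, `"matrix"`.
#' @return Numeric vector the length of `t`.
#' @name coxian-distribution
NULL

# Relative tolerance below which two total exit rates are treated as tied
# and the analytic expansion is abandoned.
DEGENERACY_TOL <- 1e-9

# Survivor values below this are treated as numerically extinct; the hazard
# returns its limit mu_n and the cumulative hazard extrapolates linearly.
SURVIVOR_FLOOR <- 1e-300

coxian_is_degenerate <- function(params, tol = DEGENERACY_TOL) {
  r <- coxian_total_rates(params)
  if (length(r) < 2L) return(FALSE)
  min(diff(sort(r))) <= tol * max(r)
}

# pi_k = (mu_k / (mu_k + lambda_k)) * prod_{j<k} lambda_j / (mu_j + lambda_j)
abs_probs_vec <- function(params) {
  lam <- params$lambda
  mu <- params$mu
  reach <- cumprod(c(1, (lam / (lam + mu))[-params$n_phases]))
  reach * mu / (lam + mu)
}

# Weights of the signed-exponential expansion: f(t) = sum_k w_k r_k e^{-r_k t},
# S(t) = sum_k w_k e^{-r_k t}, with w_k = sum_{h >= k} pi_h C_kh and
# C_kh = prod_{j <= h, j != k} r_j / (r_j - r_k). NULL when rates are tied.
analytic_weights <- function(params) {
  if (coxian_is_degenerate(params)) return(NULL)
  n <- params$n_phases
  r <- coxian_total_rates(params)
  pis <- abs_probs_vec(params)
  w <- numeric(n)
  for (k in seq_len(n)) {
    # running product over j = 1..h skipping k, accumulated as h grows
    prod_jk <- 1
    for (h in seq_len(n)) {
      if (h != k) prod_jk <- prod_jk * r[h] / (r[h] - r[k])
      if (h >= k) w[k] <- w[k] + pis[h] * prod_jk
    }
  }
  list(w = w, r = r)
}

check_times <- function(t) {
  if (!is.numeric(t) || anyNA(t)) abort("`t` must be numeric without NA.")
  if (any(t < 0)) abort(sprintf("Times must be non-negative; got %g.", min(t)))
}

expm_mat <- function(M) as.matrix(Matrix::expm(Matrix::Matrix(M)))

# Uniformization: with P = I + Q / rate_max (substochastic, nonnegative),
# p exp(Qt) v = sum_k dpois(k, rate_max * t) * (p P^k v). All terms are
# nonnegative, so the evaluation is cancellation-free — the workhorse for
# (near-)tied total rates, where the analytic expansion loses all digits.
# The series is truncated at the Poisson upper tail; if the required number
# of terms is excessive (huge rate * time products) NULL is returned and
# the caller falls back to per-point matrix exponentials.
uniformization_series <- function(params, t_max, v) {
  gen <- build_generator(params)
  rate_max <- max(coxian_total_rates(params))
  m <- rate_max * t_max
  K <- ceiling(m + 10 * sqrt(m + 1) + 30)
  if (K > 5000) return(NULL)
  P <- diag(params$n_phases) + gen$Q / rate_max
  coef <- numeric(K + 1)
  row <- gen$p
  for (k in 0:K) {
    coef[k + 1] <- sum(row * v)
    row <- row %*% P
  }
  list(coef = coef, rate_max = rate_max, K = K)
}

uniformization_eval <- function(series, t) {
  ks <- 0:series$K
  eval_block <- function(tb) {
    W <- outer(tb, ks, function(ti, k) stats::dpois(k, series$rate_max * ti))
    as.numeric(W %*% series$coef)
  }
  # chunk long time vectors to bound the Poisson weight matrix
  block <- max(1L, floor(2e6 / (series$K + 1)))
  if (length(t) <= block) return(eval_block(t))
  unlist(lapply(split(t, ceiling(seq_along(t) / block)), eval_block),
         use.names = FALSE)
}

pdf_uniformization <- function(params, t) {
  s <- uniformization_series(params, max(t), v = params$mu)
  if (is.null(s)) return(pdf_matrix_impl(params, t))
  pmax(uniformization_eval(s, t), 0)
}

survivor_uniformization <- function(params, t) {
  s <- uniformization_series(params, max(t), v = rep(1, params$n_phases))
  if (is.null(s)) return(survivor_matrix_impl(params, t))
  pmin(pmax(uniformization_eval(s, t), 0), 1)
}

pdf_matrix_impl <- function(params, t) {
  gen <- build_generator(params)
  vapply(t, function(ti) {
    v <- gen$p %*% expm_mat(gen$Q * ti) %*% gen$q
    max(as.numeric(v), 0)
  }, numeric(1))
}

survivor_matrix_impl <- function(params, t) {
  gen <- build_generator(params)
  one <- rep(1, params$n_phases)
  vapply(t, function(ti) {
    v <- as.numeric(gen$p %*% expm_mat(gen$Q * ti) %*% one)
    min(max(v, 0), 1)
  }, numeric(1))
}

#' @rdname coxian-distribution
#' @export
coxian_pdf <- function(params, t, method = c("auto", "analytic", "matrix")) {
  stopifnot(inherits(params, "coxian_params"))
  method <- match.arg(method)
  check_times(t)
  if (method == "matrix") return(pdf_matrix_impl(params, t))
  aw <- analytic_weights(params)
  if (is.null(aw)) {
    if (method == "analytic") {
      abort("Two phases share (near-)equal total exit rates; the analytic expansion is degenerate. Use method = \"matrix\".",
            class = "coxianjm_degenerate")
    }
    return(pdf_uniformization(params, t))
  }
  E <- exp(-outer(t, aw$r))           # length(t) x n
  pmax(as.numeric(E %*% (aw$w * aw$r)), 0)
}

#' @rdname coxian-distribution
#' @export
coxian_survivor <- function(params, t, method = c("auto", "analytic", "matrix")) {
  stopifnot(inherits(params, "coxian_params"))
  method <- match.arg(method)
  check_times(t)
  if (method == "matrix") return(survivor_matrix_impl(params, t))
  aw <- analytic_weights(params)
  if (is.null(aw)) {
    if (method == "analytic") {
      abort("Degenerate rates; use method = \"matrix\".", class = "coxianjm_degenerate")
    }
    return(survivor_uniformization(params, t))
  }
  E <- exp(-outer(t, aw$r))
  pmin(pmax(as.numeric(E %*% aw$w), 0), 1)
}

# log S(t), evaluated stably for large t by factoring out the slowest
# surviving exponential; used by the cumulative hazard so that deep-tail
# values extrapolate at slope min(r) instead of saturating at -log(floor).
log_survivor <- function(params, t) {
  aw <- analytic_weights(params)
  if (is.null(aw)) {
    return(log(pmax(survivor_uniformization(params, t), SURVIVOR_FLOOR)))
  }
  rmin <- min(aw$r)
  inner <- as.numeric(exp(-outer(t, aw$r - rmin)) %*% aw$w)
  out <- -rmin * t + log(pmax(inner, .Machine$double.xmin))
  pmin(out, 0)
}

#' @rdname coxian-distribution
#' @export
coxian_hazard <- function(params, t, method = c("auto", "analytic", "matrix")) {
  stopifnot(inherits(params, "coxian_params"))
  method <- match.arg(method)
  check_times(t)
  S <- coxian_survivor(params, t, method)
  f <- coxian_pdf(params, t, method)
  h <- numeric(length(t))
  dead <- S < SURVIVOR_FLOOR
  if (any(dead)) {
    inform(sprintf("Survivor underflow at %d time point(s); hazard set to its limit mu_n = %g.",
                   sum(dead), params$mu[params$n_phases]))
    h[dead] <- params$mu[params$n_phases]
  }
  h[!dead] <- f[!dead] / S[!dead]
  h
}

#' @rdname coxian-distribution
#' @export
coxian_cum_hazard <- function(params, t, method = c("auto", "analytic", "matrix")) {
  stopifnot(inherits(params, "coxian_params"))
  method <- match.arg(method)
  check_times(t)
  if (method == "auto") return(-log_survivor(params, t))
  S <- coxian_survivor(params, t, method)
  -log(pmax(S, SURVIVOR_FLOOR))
}

#' Tidy table of Coxian curves on a time grid
#'
#' @param params A [coxian_params()] object.
#' @param times Non-negative time grid (months).
#' @return A tibble with columns `time`, `density`, `survivor`, `hazard`,
#'   `cum_hazard`.
#' @export
coxian_curves <- function(params, times) {
  check_times(times)
  tibble(
    time = times,
    density = coxian_pdf(params, times),
    survivor = coxian_survivor(params, times),
    hazard = coxian_hazard(params, times),
    cum_hazard = coxian_cum_hazard(params, times)
  )
}

#' Phase-level absorption probabilities
#'
#' Probability `pi_k` that a trajectory exits the system (experiences the
#' event) from phase `k`: the chance of reaching phase `k` and then
#' absorbing rather than moving on. The probabilities sum to one and
#' depend only on rate ratios, so they are invariant under a common
#' rate-of-flow scaling.
#'
#' @param params A [coxian_params()] object.
#' @return A tibble with columns `phase` and `prob`.
#' @examples
#' absorption_probabilities(
#'   coxian_params(c(0.060, 0.467, 0), c(9.02e-11, 0.435, 0.060))
#' )
#' @export
absorption_probabilities <- function(params) {
  stopifnot(inherits(params, "coxian_params"))
  tibble(phase = seq_len(params$n_phases), prob = abs_probs_vec(params))
}

#' Partition ordered event times into phase cohorts
#'
#' Splits the `M` ordered event times into contiguous blocks in the ratio
#' `pi_1 : ... : pi_n` of the absorption probabilities: block `g` holds the
#' ordered times with index `j` in `(floor(M * cum_{g-1}), floor(M * cum_g)]`,
#' with the final cut forced to `M` so the remainder lands in the last
#' phase. Blocks with expected size below one may be empty.
#'
#' @param times Event times (sorted internally; ties permitted).
#' @param probs Absorption probabilities: a numeric vector or the tibble
#'   returned by [absorption_probabilities()].
#' @return A list of class `phase_partition` with `bounds` (tibble: `phase`,
#'   `lower`, `upper`, `size` — half-open index intervals `(lower, upper]`)
#'   and `assignments` (tibble: `j`, `time`, `phase`).
#' @export
phase_time_bounds <- function(times, probs) {
  if (is.data.frame(probs)) probs <- probs$prob
  if (!is.numeric(probs) || length(probs) < 1L) abort("`probs` must be a numeric vector.")
  if (abs(sum(probs) - 1) > 1e-6) abort("`probs` must sum to 1.")
  if (length(times) < 1L) abort("`times` must contain at least one event time.")
  M <- length(times)
  ord <- sort(times)
  n <- length(probs)
  cuts <- floor(M * cumsum(probs))
  cuts[n] <- M
  cuts <- cummax(cuts)  # guard against rounding making cuts non-monotone
  lower <- c(0L, as.integer(cuts[-n]))
  upper <- as.integer(cuts)
  phase_of <- rep.int(seq_len(n), times = upper - lower)
  structure(
    list(
      bounds = tibble(phase = seq_len(n), lower = lower, upper = upper,
                      size = upper - lower),
      assignments = tibble(j = seq_len(M), time = ord, phase = phase_of)
    ),
    class = "phase_partition"
  )
}

#' @export
print.phase_partition <- function(x, ...) {
  cat("<phase_partition>\n")
  print(x$bounds)
  invisible(x)
}

#' Simulate absorption times from a Coxian phase-type distribution
#'
#' Trajectories are simulated phase by phase: in phase `k` the dwell time is
#' exponential with rate `factor * (lambda_k + mu_k)` and the exit is an
#' absorption with probability `mu_k / (lambda_k + mu_k)`, otherwise a move
#' to phase `k + 1`. `factor` supplies an optional per-trajectory
#' rate-of-flow multiplier (recycled to length `m`).
#'
#' @param params A [coxian_params()] object.
#' @param m Number of trajectories.
#' @param seed Optional integer seed (set via [set.seed()] when supplied).
#' @param factor Positive rate multiplier(s), length 1 or `m`.
#' @return A tibble with columns `time` (absorption time, months) and
#'   `phase` (exit phase).
#' @export
sample_absorption_times <- function(params, m, seed = NULL, factor = 1) {
  stopifnot(inherits(params, "coxian_params"), m >= 1)
  if (!is.null(seed)) set.seed(seed)
  factor <- rep_len(factor, m)
  if (any(factor <= 0)) abort("`factor` must be positive.")
  n <- params$n_phases
  time <- numeric(m)
  exit_phase <- integer(m)
  active <- seq_len(m)
  for (k in seq_len(n)) {
    rate_k <- params$lambda[k] + params$mu[k]
    time[active] <- time[active] + rexp(length(active), rate_k * factor[active])
    p_absorb <- params$mu[k] / rate_k
    absorbed <- runif(length(active)) < p_absorb
    if (k == n) absorbed[] <- TRUE   # lambda_n = 0: everyone absorbs
    exit_phase[active[absorbed]] <- k
    active <- active[!absorbed]
    if (!length(active)) break
  }
  tibble(time = time, phase = exit_phase)
}
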