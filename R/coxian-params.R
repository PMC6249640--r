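#' Coxian phase-type parameters
#'
#' Container for the rates of an `n`-phase Coxian phase-type distribution:
#' sequential transition rates `lambda[k]` (phase k to k+1, per month) and
#' absorption rates `mu[k]` (phase k to the absorbing state, per month).
#' The final transition rate `lambda[n]` is identically zero — the last
#' transient phase can only absorb.
#'
#' @param lambda Numeric vector of sequential transition rates; the last
#'   entry must be exactly 0.
#' @param mu Numeric vector of absorption rates, same length as `lambda`;
#'   the last entry must be strictly positive.
#'
#' @return An object of class `coxian_params` with elements `n_phases`,
#'   `lambda` and `mu`.
#'
#' @examples
#' coxian_params(lambda = c(0.060, 0.467, 0),
#'               mu     = c(9.02e-11, 0.435, 0.060))
#' @export
coxian_params <- function(lambda, mu) {
  if (!is.numeric(lambda) || !is.numeric(mu)) {
    abort("`lambda` and `mu` must be numeric vectors.")
  }
  if (length(lambda) != length(mu)) {
    abort(sprintf("`lambda` (length %d) and `mu` (length %d) must have equal length.",
                  length(lambda), length(mu)))
  }
  n <- length(lambda)
  if (n < 1L) abort("At least one phase is required.")
  if (anyNA(lambda) || anyNA(mu)) abort("Rates must not contain NA.")
  bad_l <- which(lambda < 0)
  if (length(bad_l)) {
    abort(sprintf("Negative transition rate lambda[%d] = %g.", bad_l[1], lambda[bad_l[1]]))
  }
  bad_m <- which(mu < 0)
  if (length(bad_m)) {
    abort(sprintf("Negative absorption rate mu[%d] = %g.", bad_m[1], mu[bad_m[1]]))
  }
  if (lambda[n] != 0) {
    abort(sprintf("lambda[%d] must be exactly 0 (no onward transition from the final phase); got %g.",
                  n, lambda[n]))
  }
  if (mu[n] <= 0) {
    abort(sprintf("mu[%d] must be strictly positive (final phase must absorb).", n))
  }
  trapped <- which(lambda[-n] + mu[-n] <= 0)
  if (length(trapped)) {
    abort(sprintf("Phase %d has lambda + mu = 0 and would trap trajectories.", trapped[1]))
  }
  structure(
    list(n_phases = n, lambda = as.numeric(lambda), mu = as.numeric(mu)),
    class = "coxian_params"
  )
}

#' @export
print.coxian_params <- function(x, ...) {
  cat(sprintf("<coxian_params: %d phase%s>\n", x$n_phases, if (x$n_phases > 1) "s" else ""))
  print(tibble(phase = seq_len(x$n_phases), lambda = x$lambda, mu = x$mu))
  invisible(x)
}

# total exit rate of each phase, lambda_k + mu_k
coxian_total_rates <- function(params) params$lambda + params$mu

#' Generator system of a Coxian phase-type distribution
#'
#' Builds the transient generator matrix `Q` (bidiagonal: diagonal
#' `-(lambda_k + mu_k)`, superdiagonal `lambda_k`), the initial distribution
#' `p = (1, 0, ..., 0)` over the transient phases, and the absorption-rate
#' column `q = mu`. Row `k` of `Q` sums to `-mu_k`.
#'
#' @param params A [coxian_params()] object.
#' @return A list of class `coxian_generator` with elements `Q` (n x n
#'   matrix), `p` (length-n row vector) and `q` (length-n column vector).
#' @examples
#' build_generator(coxian_params(c(1, 0), c(0.5, 2)))
#' @export
build_generator <- function(params) {
  stopifnot(inherits(params, "coxian_params"))
  n <- params$n_phases
  Q <- diag(-(params$lambda + params$mu), nrow = n)
  if (n > 1) Q[cbind(seq_len(n - 1), seq(2, n))] <- params$lambda[-n]
  p <- c(1, rep(0, n - 1))
  structure(list(Q = Q, p = p, q = params$mu), class = "coxian_generator")
}

#' Scale all rates of a Coxian by a common factor
#'
#' Multiplies every transition and absorption rate by `factor`, the
#' "rate-of-flow" operation of the Coxian regression model. Absorption
#' probabilities are invariant under this scaling (they depend only on
#' rate ratios); time is effectively rescaled by the factor.
#'
#' @param params A [coxian_params()] object (the baseline rates).
#' @param factor A single positive number.
#' @return A new `coxian_params` with rates `factor * lambda`, `factor * mu`.
#' @examples
#' base <- coxian_params(c(0.060, 0.467, 0), c(9.02e-11, 0.435, 0.060))
#' scaled_parameters(base, 2.368)$mu[3]  # personalised final-phase hazard
#' @export
scaled_parameters <- function(params, factor) {
  stopifnot(inherits(params, "coxian_params"))
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) || factor <= 0) {
    abort("`factor` must be a single positive finite number.")
  }
  coxian_params(lambda = params$lambda * factor, mu = params$mu * factor)
}

#' Serialise Coxian parameters to a flat key-value list
#'
#' @param params A [coxian_params()] object.
#' @return A named list: `n`, `lambda_1` ... `lambda_n`, `mu_1` ... `mu_n`.
#' @seealso [coxian_params_from_config()]
#' @export
coxian_params_to_config <- function(params) {
  stopifnot(inherits(params, "coxian_params"))
  n <- params$n_phases
  c(list(n = n),
    setNames(as.list(params$lambda), paste0("lambda_", seq_len(n))),
    setNames(as.list(params$mu), paste0("mu_", seq_len(n))))
}

#' Rebuild Coxian parameters from a flat key-value list
#'
#' @param config A named list as produced by [coxian_params_to_config()].
#' @return A [coxian_params()] object.
#' @export
coxian_params_from_config <- function(config) {
  n <- as.integer(config$n)
  if (is.na(n) || n < 1L) abort("Config must contain a positive integer `n`.")
  lam <- vapply(paste0("lambda_", seq_len(n)), function(k) as.numeric(config[[k]]), numeric(1))
  mu <- vapply(paste0("mu_", seq_len(n)), function(k) as.numeric(config[[k]]), numeric(1))
  if (anyNA(lam) || anyNA(mu)) abort("Config is missing lambda_k or mu_k entries.")
  coxian_params(unname(lam), unname(mu))
}
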