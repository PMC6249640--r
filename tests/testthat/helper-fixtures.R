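# Shared fixtures. The three-phase rate set below (lambda, mu per month) is
# the renal-cohort estimate used throughout the examples: a near-zero
# first-phase absorption rate, a fast second phase and a slow final phase.

renal_params <- function() {
  coxian_params(lambda = c(0.060, 0.467, 0),
                mu     = c(9.02e-11, 0.435, 0.060))
}

# Battery of random Coxian parameter sets with well-separated total exit
# rates (pairwise gaps >= 5% of the largest), suitable for the analytic
# expansion at tight tolerances.
param_battery <- function(n_sets = 20, seed = 42) {
  set.seed(seed)
  out <- list()
  while (length(out) < n_sets) {
    n <- sample(1:4, 1)
    lam <- c(if (n > 1) exp(runif(n - 1, log(0.02), log(2))), 0)
    mu <- exp(runif(n, log(0.02), log(2)))
    p <- coxian_params(lam, mu)
    r <- sort(p$lambda + p$mu)
    if (n == 1 || min(diff(r)) > 0.05 * max(r)) out[[length(out) + 1]] <- p
  }
  out
}

surv_df <- function(times, event = 1, id = NULL) {
  tibble::tibble(id = id %||% as.character(seq_along(times)),
                 time = times, event = rep_len(event, length(times)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
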