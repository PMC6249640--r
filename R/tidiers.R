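#' Tidy a fitted Coxian model
#'
#' One row per phase: transition rate, absorption rate, absorption
#' probability. Regression fits append the covariate coefficients as
#' additional rows via `tidy(fit, coefficients = TRUE)`.
#'
#' @param x A `coxian_fit` or `coxian_reg_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy coxian_fit
#' @export
tidy.coxian_fit <- function(x, ...) {
  tibble(phase = seq_len(x$n_phases),
         lambda = x$params$lambda,
         mu = x$params$mu,
         pi = abs_probs_vec(x$params))
}

#' @rdname tidy.coxian_fit
#' @param coefficients Return the covariate coefficients instead of the
#'   per-phase rates.
#' @method tidy coxian_reg_fit
#' @export
tidy.coxian_reg_fit <- function(x, coefficients = FALSE, ...) {
  if (!coefficients) return(NextMethod())
  tibble(term = names(x$alpha),
         estimate = unname(x$alpha),
         rate_factor = exp(-unname(x$alpha)))
}

#' @method glance coxian_fit
#' @export
glance.coxian_fit <- function(x, ...) {
  tibble(n_phases = x$n_phases, loglik = x$loglik, aic = x$aic, bic = x$bic,
         n_free = x$n_free, nobs = x$n_obs, n_events = x$n_events,
         converged = x$converged, n_restarts = x$n_restarts, seed = x$seed)
}

#' @method tidy coxian_selection
#' @export
tidy.coxian_selection <- function(x, ...) x$trace

#' @method glance coxian_selection
#' @export
glance.coxian_selection <- function(x, ...) {
  tibble(chosen_n = x$chosen_n, n_fitted = nrow(x$trace),
         alpha_level = x$alpha_level)
}

#' @method tidy coxian_boot
#' @export
tidy.coxian_boot <- function(x, ...) x$summary

#' @method glance coxian_boot
#' @export
glance.coxian_boot <- function(x, ...) {
  tibble(B = x$B, B_used = x$B_used, dropped = x$dropped,
         status = x$status, seed = x$seed)
}

#' @method tidy lme_stage
#' @export
tidy.lme_stage <- function(x, ...) {
  tibble(term = names(x$beta), estimate = unname(x$beta))
}

#' @method glance lme_stage
#' @export
glance.lme_stage <- function(x, ...) {
  tibble(loglik = x$loglik, df = x$df, sigma2 = x$sigma2,
         var_b0 = x$D[1, 1],
         var_b1 = if (nrow(x$D) > 1) x$D[2, 2] else NA_real_,
         cor_b0_b1 = if (nrow(x$D) > 1 && x$D[1, 1] > 0 && x$D[2, 2] > 0) {
           x$D[1, 2] / sqrt(x$D[1, 1] * x$D[2, 2])
         } else NA_real_,
         n_subjects = x$n_subjects, reml = x$reml)
}
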