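#' Log-likelihood of a Coxian phase-type sample
#'
#' Sums `log f(t_i)` over events and `log S(t_i)` over right-censored
#' records. The analytic density expansion is used when the total exit
#' rates are well separated, the matrix-exponential form otherwise; values
#' that underflow are floored so the result is always finite.
#'
#' @param params A [coxian_params()] object.
#' @param data A data frame with columns `time` (positive, months) and
#'   `event` (1 = event observed, 0 = right-censored). An `id` column is
#'   permitted and ignored here.
#' @return A single log-likelihood value.
#' @export
coxian_loglik <- function(params, data) {
  data <- validate_survival(data)
  loglik_vectors(params, data$time, data$event)
}

# Nudge each phase's rates by a distinct relative offset so that tied total
# rates separate; used only inside the optimiser, where a ~1e-6 relative
# rate shift is far below the attainable precision but restores the fast
# analytic expansion near tied-rate optima.
perturb_params <- function(params) {
  r <- coxian_total_rates(params)
  delta <- 1e-6 * max(r)
  o <- order(r)
  r_new <- r
  prev <- -Inf
  for (i in o) {
    if (r_new[i] <= prev + delta) r_new[i] <- prev + delta
    prev <- r_new[i]
  }
  s <- r_new / r
  coxian_params(params$lambda * s, params$mu * s)
}

# core likelihood on pre-validated vectors; `fast = TRUE` is the optimiser
# hot path (perturbed analytic expansion near rate ties), `fast = FALSE`
# evaluates exactly (analytic, else uniformization / matrix exponential)
loglik_vectors <- function(params, time, event, fast = FALSE) {
  aw <- analytic_weights(params)
  if (is.null(aw) && fast) aw <- analytic_weights(perturb_params(params))
  ev <- event == 1
  if (is.null(aw)) {
    ll <- 0
    if (any(ev)) ll <- ll + sum(log(pmax(coxian_pdf(params, time[ev]), 1e-300)))
    if (any(!ev)) ll <- ll + sum(log_survivor(params, time[!ev]))
    return(ll)
  }
  ll <- 0
  if (any(ev)) {
    f <- pmax(as.numeric(exp(-outer(time[ev], aw$r)) %*% (aw$w * aw$r)), 0)
    ll <- ll + sum(log(pmax(f, 1e-300)))
  }
  if (any(!ev)) {
    tc <- time[!ev]
    rmin <- min(aw$r)
    inner <- as.numeric(exp(-outer(tc, aw$r - rmin)) %*% aw$w)
    ll <- ll + sum(pmin(-rmin * tc + log(pmax(inner, .Machine$double.xmin)), 0))
  }
  ll
}

# ---- internal optimisation machinery -------------------------------------

LOG_RATE_MIN <- -30
LOG_RATE_MAX <- 30

# free parameters: log(lambda_1..lambda_{n-1}), log(mu_1..mu_n)
theta_to_params <- function(theta, n) {
  theta <- pmin(pmax(theta, LOG_RATE_MIN), LOG_RATE_MAX)
  lam <- if (n > 1) c(exp(theta[seq_len(n - 1)]), 0) else 0
  mu <- exp(theta[n:(2 * n - 1)])
  coxian_params(lam, mu)
}

params_to_theta <- function(params) {
  n <- params$n_phases
  lam <- pmax(params$lambda, exp(LOG_RATE_MIN))
  mu <- pmax(params$mu, exp(LOG_RATE_MIN))
  c(if (n > 1) log(lam[seq_len(n - 1)]), log(mu))
}

# Draw initial log-rates scaled to the sample mean time, per restart.
draw_start <- function(n_free, tbar) {
  runif(n_free, min = log(0.1 / tbar), max = log(10 / tbar))
}

# Multi-start Nelder-Mead (Brent in one dimension) on a penalised negative
# log-likelihood. `starts` is a list of numeric vectors.
multistart_optim <- function(objective, starts, maxit = 20000, reltol = 1e-8) {
  n_free <- length(starts[[1]])
  run_one <- function(s) {
    if (n_free == 1L) {
      o <- optim(s, objective, method = "Brent",
                 lower = LOG_RATE_MIN, upper = LOG_RATE_MAX,
                 control = list(maxit = maxit))
      # polish with optimize for high relative accuracy
      op <- optimize(objective, c(max(s - 15, LOG_RATE_MIN), min(s + 15, LOG_RATE_MAX)),
                     tol = 1e-12)
      if (op$objective < o$value) {
        o$par <- op$minimum
        o$value <- op$objective
      }
      o$convergence <- 0L
      o
    } else {
      optim(s, objective, method = "Nelder-Mead",
            control = list(maxit = maxit, reltol = reltol))
    }
  }
  results <- lapply(starts, run_one)
  values <- vapply(results, function(r) r$value, numeric(1))
  best <- which.min(values)
  list(best = results[[best]], best_index = best,
       converged = results[[best]]$convergence == 0L,
       any_converged = any(vapply(results, function(r) r$convergence == 0L, logical(1))))
}

new_coxian_fit <- function(params, loglik, n_free, data, opt, n_restarts, seed,
                           class = "coxian_fit", extra = list()) {
  M <- nrow(data)
  structure(
    c(list(
      params = params,
      loglik = loglik,
      aic = -2 * loglik + 2 * n_free,
      bic = -2 * loglik + n_free * log(M),
      n_phases = params$n_phases,
      n_free = n_free,
      n_restarts = n_restarts,
      best_start_index = opt$best_index,
      converged = opt$converged,
      seed = seed,
      n_obs = M,
      n_events = sum(data$event),
      data = data
    ), extra),
    class = class
  )
}

#' Fit a Coxian phase-type distribution by maximum likelihood
#'
#' Maximises the log-likelihood over the `2n - 1` free rates using
#' multi-start Nelder-Mead (Brent line search when `n_phases = 1`) on the
#' unconstrained log-rate scale. Initial log-rates are drawn uniformly on
#' `[log(0.1 / tbar), log(10 / tbar)]`, `tbar` the sample mean time, so the
#' search is scaled to the data; the fit is notoriously sensitive to
#' starting values, hence the restarts.
#'
#' @param data Data frame with columns `id`, `time`, `event` (an `id`
#'   column is optional here).
#' @param n_phases Number of transient phases.
#' @param n_restarts Number of random restarts (default 50).
#' @param seed Integer seed controlling the restart draws.
#' @param extra_starts Optional list of additional starting vectors on the
#'   log-rate scale (used internally to warm-start nested searches).
#' @param maxit,reltol Nelder-Mead control parameters.
#' @return An object of class `coxian_fit` with elements `params`,
#'   `loglik`, `aic`, `bic`, `converged`, `best_start_index`, `seed`, the
#'   data, and bookkeeping fields. Methods: [tidy()], [glance()],
#'   [autoplot()].
#' @examples
#' sim <- sample_absorption_times(coxian_params(0, 0.5), 200, seed = 1)
#' fit <- fit_coxian(data.frame(time = sim$time, event = 1), n_phases = 1)
#' 1 / mean(sim$time)  # closed-form exponential MLE
#' fit$params$mu
#' @export
fit_coxian <- function(data, n_phases, n_restarts = 50, seed = 1,
                       extra_starts = NULL, maxit = 20000, reltol = 1e-8) {
  data <- validate_survival(data)
  stopifnot(n_phases >= 1, n_restarts >= 1)
  set.seed(seed)
  n <- as.integer(n_phases)
  n_free <- 2L * n - 1L
  tbar <- mean(data$time)
  time <- data$time
  event <- data$event
  objective <- function(theta) {
    ll <- tryCatch(loglik_vectors(theta_to_params(theta, n), time, event,
                                  fast = TRUE),
                   error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }
  starts <- c(replicate(n_restarts, draw_start(n_free, tbar), simplify = FALSE),
              extra_starts)
  opt <- multistart_optim(objective, starts, maxit = maxit, reltol = reltol)
  if (!opt$any_converged) {
    abort("No restart of the Coxian fit converged; best partial result attached.",
          class = "coxianjm_fit_failure", partial = opt$best)
  }
  params <- theta_to_params(opt$best$par, n)
  new_coxian_fit(params, loglik_vectors(params, time, event), n_free, data, opt,
                 n_restarts = length(starts), seed = seed)
}

#' Choose the number of Coxian phases sequentially
#'
#' Fits `n = 1, 2, ...` phases, comparing each model to the previous one
#' with a likelihood-ratio test on 2 degrees of freedom (each extra phase
#' adds one transition and one absorption rate) alongside AIC and BIC. The
#' search stops early when the LRT is non-significant at `alpha_level`
#' *and* the AIC worsens; the chosen model is the last one accepted. One
#' restart of each search is warm-started from the previous solution
#' padded with a vanishing extra phase, which enforces the likelihood
#' nesting.
#'
#' @param data Data frame with columns `time`, `event` (optionally `id`).
#' @param max_phases Largest number of phases to consider (at least 2).
#' @param alpha_level Significance level for the sequential LRT.
#' @param effects Optional per-subject random-effect table (`id`, `b0`,
#'   `b1`); when supplied, Coxian *regression* models (two extra covariate
#'   parameters) are compared instead of plain Coxians.
#' @inheritParams fit_coxian
#' @return An object of class `coxian_selection`: list with `trace` (tibble
#'   of per-`n` results), `fits` (list of fit objects), `chosen_n`, and
#'   `best_fit`.
#' @export
select_phases <- function(data, max_phases, alpha_level = 0.05,
                          n_restarts = 50, seed = 1, effects = NULL,
                          maxit = 20000, reltol = 1e-8) {
  data <- validate_survival(data)
  stopifnot(max_phases >= 2)
  fits <- vector("list", max_phases)
  rows <- vector("list", max_phases)
  chosen <- 1L
  prev <- NULL
  for (n in seq_len(max_phases)) {
    warm <- if (!is.null(prev)) list(pad_theta(prev, effects)) else NULL
    fit_n <- tryCatch({
      if (is.null(effects)) {
        fit_coxian(data, n, n_restarts = n_restarts, seed = seed + n,
                   extra_starts = warm, maxit = maxit, reltol = reltol)
      } else {
        fit_coxian_regression(data, effects, n, n_restarts = n_restarts,
                              seed = seed + n, extra_starts = warm,
                              maxit = maxit, reltol = reltol)
      }
    }, error = function(e) e)
    if (inherits(fit_n, "error")) {
      rows[[n]] <- tibble(n_phases = n, loglik = NA_real_, aic = NA_real_,
                          bic = NA_real_, lrt_stat = NA_real_, lrt_df = 2L,
                          lrt_p = NA_real_, converged = FALSE, failed = TRUE)
      break
    }
    fits[[n]] <- fit_n
    lrt_stat <- lrt_p <- NA_real_
    if (n > 1 && !is.null(fits[[n - 1]])) {
      lrt_stat <- 2 * (fit_n$loglik - fits[[n - 1]]$loglik)
      lrt_p <- pchisq(max(lrt_stat, 0), df = 2, lower.tail = FALSE)
    }
    rows[[n]] <- tibble(n_phases = n, loglik = fit_n$loglik, aic = fit_n$aic,
                        bic = fit_n$bic, lrt_stat = lrt_stat, lrt_df = 2L,
                        lrt_p = lrt_p, converged = fit_n$converged, failed = FALSE)
    if (n > 1) {
      improved <- (!is.na(lrt_p) && lrt_p <= alpha_level) ||
        fit_n$aic < fits[[n - 1]]$aic
      if (!improved) break
      chosen <- n
    }
    prev <- fit_n
  }
  trace <- list_rbind(rows[!vapply(rows, is.null, logical(1))])
  structure(
    list(trace = trace, fits = fits, chosen_n = chosen,
         best_fit = fits[[chosen]], alpha_level = alpha_level),
    class = "coxian_selection"
  )
}

# Pad an (n-1)-phase solution to an n-phase starting vector: the old final
# phase gains a vanishing onward rate into a new final phase that inherits
# its absorption rate, leaving the density essentially unchanged.
pad_theta <- function(fit, effects = NULL) {
  p <- fit$params
  n_old <- p$n_phases
  eps <- max(p$mu[n_old] * 1e-4, exp(LOG_RATE_MIN))
  lam_head <- if (n_old > 1) p$lambda[seq_len(n_old - 1)] else numeric(0)
  lam_new <- c(lam_head, eps, 0)
  mu_new <- c(p$mu, p$mu[n_old])
  theta <- params_to_theta(coxian_params(lam_new, mu_new))
  if (!is.null(effects)) theta <- c(theta, fit$alpha %||% c(0, 0))
  theta
}

#' @export
print.coxian_selection <- function(x, ...) {
  cat(sprintf("<coxian_selection: chose %d phase%s>\n", x$chosen_n,
              if (x$chosen_n > 1) "s" else ""))
  print(x$trace)
  invisible(x)
}

#' @export
print.coxian_fit <- function(x, ...) {
  cat(sprintf("<%s: %d phases, logLik %.3f, AIC %.3f, %s>\n",
              class(x)[1], x$n_phases, x$loglik, x$aic,
              if (x$converged) "converged" else "NOT converged"))
  print(x$params)
  if (!is.null(x$alpha)) {
    cat(sprintf("alpha1 = %.4f (factor %.4f), alpha2 = %.4f (factor %.4f)\n",
                x$alpha[1], exp(-x$alpha[1]), x$alpha[2], exp(-x$alpha[2])))
  }
  invisible(x)
}
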