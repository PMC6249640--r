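#' Configuration of a two-stage run
#'
#' Exactly one input source must be given: CSV paths (`longitudinal_path` +
#' `survival_path`, or `effects_path` + `survival_path` to skip Stage 1),
#' or a synthetic [cohort_config()] via `preset`.
#'
#' @param longitudinal_path,survival_path,effects_path Input CSV paths.
#' @param preset A [cohort_config()] to simulate instead of reading files.
#' @param fixed Fixed-effect covariate columns for Stage 1.
#' @param max_phases Largest number of Coxian phases considered.
#' @param n_restarts Random restarts per phase-number fit.
#' @param bootstrap_B Bootstrap replicates (0 disables the bootstrap).
#' @param seed Integer seed governing every stochastic step.
#' @param out_dir Output directory for [write_results()] (`NULL` to skip
#'   writing).
#' @param curve_ids Subject ids for individual curve tables (default: none).
#' @param curve_times Time grid for emitted curves.
#' @return A list of class `two_stage_config`.
#' @export
two_stage_config <- function(longitudinal_path = NULL, survival_path = NULL,
                             effects_path = NULL, preset = NULL,
                             fixed = character(), max_phases = 5,
                             n_restarts = 50, bootstrap_B = 500, seed = 1,
                             out_dir = NULL, curve_ids = character(),
                             curve_times = seq(0, 120, by = 1)) {
  from_files <- !is.null(survival_path)
  if (identical(from_files, !is.null(preset))) {
    abort("Supply exactly one of: input paths or a synthetic `preset`.")
  }
  if (from_files && is.null(longitudinal_path) && is.null(effects_path)) {
    abort("With `survival_path`, supply `longitudinal_path` or `effects_path`.")
  }
  structure(
    list(longitudinal_path = longitudinal_path, survival_path = survival_path,
         effects_path = effects_path, preset = preset, fixed = fixed,
         max_phases = max_phases, n_restarts = n_restarts,
         bootstrap_B = bootstrap_B, seed = as.integer(seed),
         out_dir = out_dir, curve_ids = curve_ids, curve_times = curve_times),
    class = "two_stage_config"
  )
}

#' Run the full two-stage analysis
#'
#' Stage 1 fits the linear mixed effects model and predicts per-subject
#' random effects (skipped when an effects table is supplied directly);
#' Stage 2 selects the number of Coxian phases for the regression model,
#' bootstraps the covariate effects, and derives absorption probabilities,
#' the phase partition of the ordered event times, and survivor/hazard
#' curves. All stochastic steps derive from `config$seed`.
#'
#' @param config A [two_stage_config()].
#' @return A list of class `two_stage_result` with elements `lme`,
#'   `effects`, `selection`, `fit`, `bootstrap`, `absorption`, `partition`,
#'   `curves`, `config`, `seed`, `version`. Written to `config$out_dir`
#'   when set.
#' @export
run_two_stage <- function(config) {
  stopifnot(inherits(config, "two_stage_config"))
  if (!is.null(config$preset)) {
    cohort <- generate_cohort(config$preset)
    longitudinal <- cohort$longitudinal
    survival <- cohort$survival
    effects <- NULL
  } else {
    survival <- read_survival(config$survival_path)
    longitudinal <- if (!is.null(config$longitudinal_path)) {
      read_longitudinal(config$longitudinal_path)
    }
    effects <- if (!is.null(config$effects_path)) read_effects(config$effects_path)
  }

  lme <- NULL
  if (is.null(effects)) {
    lme <- fit_lme_stage(longitudinal, fixed = config$fixed)
    effects <- predict_random_effects(lme)
  }

  selection <- select_phases(survival, max_phases = config$max_phases,
                             n_restarts = config$n_restarts,
                             seed = config$seed, effects = effects)
  fit <- selection$best_fit

  boot <- NULL
  if (config$bootstrap_B >= 2) {
    boot <- bootstrap_coxian(fit, B = config$bootstrap_B,
                             seed = config$seed + 1000L)
  }

  absorption <- absorption_probabilities(fit$params)
  events <- filter(fit$data, .data$event == 1)
  partition <- if (nrow(events)) phase_time_bounds(events$time, absorption)

  pop_curves <- coxian_curves(fit$params, config$curve_times)
  ind_curves <- NULL
  if (length(config$curve_ids)) {
    sel_eff <- filter(effects, .data$id %in% config$curve_ids)
    if (nrow(sel_eff)) ind_curves <- individual_curves(fit, sel_eff, config$curve_times)
  }

  result <- structure(
    list(lme = lme, effects = effects, selection = selection, fit = fit,
         bootstrap = boot, absorption = absorption, partition = partition,
         population_curves = pop_curves, individual_curves = ind_curves,
         config = config, seed = config$seed,
         version = as.character(packageVersion("coxianjm"))),
    class = "two_stage_result"
  )
  if (!is.null(config$out_dir)) write_results(result, config$out_dir)
  result
}

#' @export
print.two_stage_result <- function(x, ...) {
  cat("<two_stage_result>\n")
  cat(sprintf("Chosen phases: %d\n", x$selection$chosen_n))
  print(x$fit)
  cat("Absorption probabilities:\n")
  print(x$absorption)
  if (!is.null(x$bootstrap)) print(x$bootstrap)
  invisible(x)
}

#' Write a two-stage results bundle
#'
#' Emits a machine-readable JSON bundle (`results.json`), curve CSVs
#' (`population_curves.csv`, `individual_curves.csv` when present,
#' `effects.csv`) and a human-readable text report (`report.txt`) into
#' `dir`.
#'
#' @param result A `two_stage_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(result, dir) {
  stopifnot(inherits(result, "two_stage_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fit <- result$fit
  bundle <- list(
    version = result$version,
    seed = result$seed,
    chosen_n_phases = result$selection$chosen_n,
    params = coxian_params_to_config(fit$params),
    alpha = as.list(fit$alpha),
    loglik = fit$loglik, aic = fit$aic, bic = fit$bic,
    absorption = as.list(setNames(result$absorption$prob,
                                  paste0("pi_", result$absorption$phase))),
    selection_trace = result$selection$trace,
    partition = if (!is.null(result$partition)) result$partition$bounds,
    bootstrap = if (!is.null(result$bootstrap)) {
      list(B = result$bootstrap$B, B_used = result$bootstrap$B_used,
           status = result$bootstrap$status, summary = result$bootstrap$summary)
    }
  )
  jsonlite::write_json(bundle, file.path(dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  readr::write_csv(result$population_curves, file.path(dir, "population_curves.csv"))
  if (!is.null(result$individual_curves)) {
    readr::write_csv(result$individual_curves, file.path(dir, "individual_curves.csv"))
  }
  readr::write_csv(result$effects, file.path(dir, "effects.csv"))

  con <- file(file.path(dir, "report.txt"), open = "wt")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("Two-stage Coxian phase-type regression analysis")
  w("package coxianjm %s, seed %d", result$version, result$seed)
  w("")
  w("Chosen number of phases: %d", result$selection$chosen_n)
  for (k in seq_len(fit$n_phases)) {
    w("phase %d: lambda = %.6g, mu = %.6g, pi = %.6g", k,
      fit$params$lambda[k], fit$params$mu[k], result$absorption$prob[k])
  }
  if (!is.null(fit$alpha)) {
    w("alpha1 = %.4f  (rate-of-flow factor exp(-alpha1) = %.4f)",
      fit$alpha[1], exp(-fit$alpha[1]))
    w("alpha2 = %.4f  (rate-of-flow factor exp(-alpha2) = %.4f)",
      fit$alpha[2], exp(-fit$alpha[2]))
  }
  if (!is.null(result$bootstrap)) {
    s <- result$bootstrap$summary
    for (i in seq_len(nrow(s))) {
      w("%s: %.4f (se %.4f), 95%% CI (%.4f, %.4f)%s", s$term[i], s$estimate[i],
        s$se[i], s$conf_low[i], s$conf_high[i],
        if (s$significant[i]) " *significant*" else "")
    }
  }
  if (!is.null(result$partition)) {
    b <- result$partition$bounds
    for (i in seq_len(nrow(b))) {
      w("phase %d ordered-event-time block: (%d, %d], size %d",
        b$phase[i], b$lower[i], b$upper[i], b$size[i])
    }
  }
  w("")
  w("Model selection trace:")
  tr <- result$selection$trace
  for (i in seq_len(nrow(tr))) {
    w("n = %d: logLik %.3f, AIC %.3f, BIC %.3f, LRT p %s", tr$n_phases[i],
      tr$loglik[i], tr$aic[i], tr$bic[i],
      ifelse(is.na(tr$lrt_p[i]), "-", sprintf("%.4g", tr$lrt_p[i])))
  }
  invisible(dir)
}
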