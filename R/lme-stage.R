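#' Stage 1: linear mixed effects model for the longitudinal biomarker
#'
#' Fits `response ~ time + <fixed covariates> + (1 + time | id)`, the
#' random-intercept-and-slope model in which each subject deviates from
#' the population-average intercept and slope. Continuous covariates
#' (numeric columns with more than two distinct values) are centred about
#' their sample means; the centring constants are stored so downstream
#' predictions are reproducible. Estimation is maximum likelihood by
#' default (`reml = FALSE`), keeping likelihood-ratio tests on fixed
#' effects valid; REML is available via the flag. Fitting delegates to
#' [lme4::lmer()] — this stage is standard methodology.
#'
#' @param data Longitudinal data frame: `id`, `time` (months), `response`,
#'   plus any covariate columns named in `fixed`.
#' @param fixed Character vector of fixed-effect covariate column names
#'   (besides `time`, which is always included).
#' @param reml Use REML instead of ML.
#' @param random Random-effect structure: `"intercept_slope"` (default) or
#'   `"intercept"` (used for nested-model LRTs).
#' @return An object of class `lme_stage`: `beta` (fixed effects), `D`
#'   (random-effect covariance), `sigma2` (residual variance), `loglik`,
#'   `df`, `centers`, and the underlying `lmerMod` as `model`.
#' @export
fit_lme_stage <- function(data, fixed = character(), reml = FALSE,
                          random = c("intercept_slope", "intercept")) {
  data <- validate_longitudinal(data)
  random <- match.arg(random)
  missing_cols <- setdiff(fixed, names(data))
  if (length(missing_cols)) {
    abort(sprintf("Fixed-effect column(s) not in data: %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  centers <- numeric(0)
  for (v in fixed) {
    x <- data[[v]]
    if (is.numeric(x) && length(unique(x)) > 2L) {
      centers[v] <- mean(x)
      data[[v]] <- x - centers[v]
    }
  }
  rhs <- c("time", fixed)
  mm <- model.matrix(stats::reformulate(rhs), data)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    dropped <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    abort(sprintf("Design matrix is rank deficient; collinear column(s): %s.",
                  paste(dropped, collapse = ", ")))
  }
  re_term <- if (random == "intercept_slope") "(1 + time | id)" else "(1 | id)"
  form <- stats::as.formula(
    paste("response ~", paste(rhs, collapse = " + "), "+", re_term))
  model <- lme4::lmer(form, data = data, REML = reml,
                      control = lme4::lmerControl(check.conv.singular = "ignore",
                                                  calc.derivs = FALSE))
  conv <- model@optinfo$conv$opt
  if (!is.null(conv) && conv != 0) {
    abort(sprintf("Mixed-model optimiser failed (code %s): %s", conv,
                  paste(unlist(model@optinfo$message), collapse = "; ")))
  }
  vc <- lme4::VarCorr(model)
  D <- matrix(c(vc$id), nrow = nrow(vc$id), dimnames = dimnames(vc$id))
  ll <- logLik(model)
  structure(
    list(model = model,
         beta = lme4::fixef(model),
         D = D,
         sigma2 = stats::sigma(model)^2,
         loglik = as.numeric(ll),
         df = attr(ll, "df"),
         reml = reml,
         random = random,
         fixed = fixed,
         centers = centers,
         data = data,
         n_subjects = length(unique(data$id))),
    class = "lme_stage"
  )
}

#' @export
print.lme_stage <- function(x, ...) {
  cat(sprintf("<lme_stage: %s, %d subjects, logLik %.3f>\n",
              if (x$reml) "REML" else "ML", x$n_subjects, x$loglik))
  cat("Fixed effects:\n")
  print(x$beta)
  cat("Random-effect covariance D:\n")
  print(x$D)
  cat(sprintf("Residual variance sigma2 = %.4f\n", x$sigma2))
  invisible(x)
}

#' Predict subject-specific random effects (empirical BLUPs)
#'
#' Computes, per subject, `b_i = D Z_i' V_i^{-1} (y_i - X_i beta)` with
#' `V_i = Z_i D Z_i' + sigma2 I` — the best linear unbiased predictor of
#' the random intercept and slope given the Stage-1 estimates. Predictions
#' shrink toward zero as the random-effect variances shrink; with `D = 0`
#' every prediction is exactly zero.
#'
#' @param fit An `lme_stage` object.
#' @param data Optional new longitudinal data (same schema; covariates are
#'   centred with the stored Stage-1 constants). Defaults to the training
#'   data.
#' @return A tibble `id`, `b0`, `b1` with one row per subject (`b1 = 0`
#'   under a random-intercept-only model).
#' @export
predict_random_effects <- function(fit, data = NULL) {
  stopifnot(inherits(fit, "lme_stage"))
  if (is.null(data)) {
    data <- fit$data
  } else {
    data <- validate_longitudinal(data)
    for (v in names(fit$centers)) data[[v]] <- data[[v]] - fit$centers[v]
  }
  rhs <- c("time", fit$fixed)
  X <- model.matrix(stats::reformulate(rhs), data)
  resid <- data$response - as.numeric(X %*% fit$beta)
  has_slope <- fit$random == "intercept_slope"
  D <- fit$D
  ids <- unique(data$id)
  out <- matrix(0, nrow = length(ids), ncol = 2,
                dimnames = list(NULL, c("b0", "b1")))
  for (i in seq_along(ids)) {
    rows <- which(data$id == ids[i])
    Zi <- if (has_slope) cbind(1, data$time[rows]) else matrix(1, length(rows), 1)
    Vi <- Zi %*% D %*% t(Zi) + fit$sigma2 * diag(length(rows))
    bi <- D %*% t(Zi) %*% solve(Vi, resid[rows])
    out[i, seq_len(nrow(D))] <- as.numeric(bi)
  }
  tibble(id = ids, b0 = out[, "b0"], b1 = out[, "b1"])
}

#' Likelihood-ratio test for nested random-effect structures
#'
#' Compares two Stage-1 fits on the same data and fixed effects, e.g.
#' random intercept only versus random intercept and slope. The usual
#' chi-squared reference is used; note that variance parameters on the
#' boundary make this test conservative.
#'
#' @param fit_nested,fit_full `lme_stage` objects, `fit_nested` the
#'   smaller model.
#' @return A tibble with `statistic`, `df`, `p_value`.
#' @export
lrt_random_effects <- function(fit_nested, fit_full) {
  stopifnot(inherits(fit_nested, "lme_stage"), inherits(fit_full, "lme_stage"))
  if (!identical(fit_nested$fixed, fit_full$fixed)) {
    abort("Models are not nested: fixed-effect specifications differ.")
  }
  if (fit_nested$df > fit_full$df) {
    abort("Models are not nested: the first fit has more parameters.")
  }
  stat <- max(2 * (fit_full$loglik - fit_nested$loglik), 0)
  df <- fit_full$df - fit_nested$df
  tibble(statistic = stat, df = df,
         p_value = if (df > 0) pchisq(stat, df, lower.tail = FALSE) else NA_real_)
}
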