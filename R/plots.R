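#' Plot the four Coxian curves
#'
#' Density, survivor, hazard and cumulative hazard of a parameter set on a
#' time grid, facetted.
#'
#' @param object A [coxian_params()] object.
#' @param times Time grid (months); default 0-120 by 0.5.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.coxian_params <- function(object, times = seq(0, 120, by = 0.5), ...) {
  long <- tidyr::pivot_longer(coxian_curves(object, times),
                              cols = c("density", "survivor", "hazard", "cum_hazard"),
                              names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "time (months)", y = NULL,
                  title = "Coxian phase-type distribution") +
    ggplot2::theme_minimal()
}

#' Plot a fitted Coxian against the data
#'
#' Overlays the fitted survivor curve on the Kaplan-Meier estimate of the
#' sample the model was fitted to (regression fits show the baseline,
#' i.e. population-average, curve).
#'
#' @param object A `coxian_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.coxian_fit <- function(object, ...) {
  data <- object$data
  grid <- seq(0, max(data$time) * 1.05, length.out = 200)
  fitted <- tibble(time = grid,
                   survivor = coxian_survivor(object$params, grid),
                   curve = "fitted Coxian")
  p <- ggplot2::ggplot(fitted, ggplot2::aes(x = .data$time, y = .data$survivor)) +
    ggplot2::geom_line(ggplot2::aes(colour = .data$curve))
  if (requireNamespace("survival", quietly = TRUE)) {
    km <- survival::survfit(survival::Surv(data$time, data$event) ~ 1)
    emp <- tibble(time = km$time, survivor = km$surv, curve = "Kaplan-Meier")
    p <- p + ggplot2::geom_step(data = emp,
                                ggplot2::aes(colour = .data$curve))
  }
  p + ggplot2::labs(x = "time (months)", y = "survival probability",
                    colour = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot bootstrap replicate distributions of the rate-of-flow factors
#'
#' @param object A `coxian_boot`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.coxian_boot <- function(object, ...) {
  reps <- filter(object$replicates, .data$converged)
  long <- tidyr::pivot_longer(
    mutate(reps, exp_neg_alpha1 = exp(-.data$alpha1),
           exp_neg_alpha2 = exp(-.data$alpha2)),
    cols = c("exp_neg_alpha1", "exp_neg_alpha2"),
    names_to = "term", values_to = "factor")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$factor)) +
    ggplot2::geom_histogram(bins = 30, fill = "#2c7fb8", colour = "white") +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::facet_wrap(~term, scales = "free_x") +
    ggplot2::labs(x = "bootstrap replicate exp(-alpha)", y = "count") +
    ggplot2::theme_minimal()
}

#' Population-average and individual-specific curves
#'
#' Plots the baseline survivor (or hazard) curve of a fitted regression
#' model together with personalised curves for the requested subjects.
#'
#' @param fit A `coxian_reg_fit`.
#' @param effects Data frame `id`, `b0`, `b1` of subjects to display.
#' @param times Time grid (months).
#' @param quantity `"survivor"`, `"hazard"` or `"cum_hazard"`.
#' @return A ggplot.
#' @export
plot_individual_curves <- function(fit, effects, times = seq(0, 120, by = 0.5),
                                   quantity = c("survivor", "hazard", "cum_hazard")) {
  quantity <- match.arg(quantity)
  ind <- individual_curves(fit, effects, times)
  base <- coxian_curves(fit$params, times)
  base$id <- "population average"
  cols <- c("id", "time", quantity)
  both <- bind_rows(ind[cols], base[cols])
  ggplot2::ggplot(both, ggplot2::aes(x = .data$time, y = .data[[quantity]],
                                     colour = .data$id)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (months)", y = quantity, colour = "subject") +
    ggplot2::theme_minimal()
}
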