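# ggplot2 displays for prediction bands, fits and residual diagnostics.

#' Plot visual-predictive-check bands
#'
#' Ribbon of the simulated prediction interval with the simulated median,
#' faceted by dose group; pass the analysis dataset to overlay observations.
#'
#' @param object A `vpc_bands` tibble from [simulate_prediction_bands()].
#' @param data Optional dataset tibble; its observation rows are overlaid.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot vpc_bands
#' @export
autoplot.vpc_bands <- function(object, data = NULL, ...) {
  probs <- attr(object, "probs") %||% c(0.025, 0.5, 0.975)
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median), colour = "steelblue4") +
    ggplot2::facet_wrap(~ dose_group, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(
      x = "Time (h)", y = "Plasma ascorbate (mM)",
      title = "Monte Carlo prediction distribution",
      subtitle = sprintf("%g%% interval, %d simulated individuals per group",
                         100 * (probs[3] - probs[1]),
                         attr(object, "n_simulated") %||% NA)
    ) +
    ggplot2::theme_minimal()
  if (!is.null(data)) {
    obs <- data[data$EVID == 0L & data$CENS == 0L, ]
    obs$dose_group <- obs$DOSEGRP
    p <- p + ggplot2::geom_point(
      data = obs, ggplot2::aes(x = .data$TIME, y = .data$DV),
      colour = "grey30", size = 0.8, alpha = 0.6
    )
  }
  p
}

#' Plot the SAEM convergence trace
#'
#' One panel per estimated quantity, with the exploratory/smoothing phase
#' boundary marked.
#'
#' @param object A [saem()] fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot saem_fit
#' @export
autoplot.saem_fit <- function(object, ...) {
  tr <- tidyr::pivot_longer(object$trace, -c("iteration", "phase"),
                            names_to = "parameter", values_to = "value")
  k1 <- object$settings$n_exploratory
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue4") +
    ggplot2::geom_vline(xintercept = k1, linetype = "dashed", colour = "grey50") +
    ggplot2::facet_wrap(~ parameter, scales = "free_y") +
    ggplot2::labs(x = "SAEM iteration", y = "Estimate",
                  title = "SAEM parameter search",
                  subtitle = "Dashed line: end of the exploratory phase") +
    ggplot2::theme_minimal()
}

#' Residual diagnostic panels
#'
#' Normal quantile-quantile plot of NPDE or IWRES values.
#'
#' @param residuals Tibble from [npde()] or
#'   [individual_weighted_residuals()].
#' @param column Residual column to plot (`"npde"` or `"IWRES"`).
#' @return A ggplot object.
#' @export
plot_residual_qq <- function(residuals, column = c("npde", "IWRES")) {
  column <- match.arg(column)
  if (!column %in% names(residuals)) {
    abort(sprintf("Column `%s` not found in `residuals`.", column))
  }
  ggplot2::ggplot(residuals, ggplot2::aes(sample = .data[[column]])) +
    ggplot2::geom_qq(colour = "steelblue4", alpha = 0.7) +
    ggplot2::geom_qq_line(colour = "grey40") +
    ggplot2::labs(x = "Theoretical N(0,1) quantiles",
                  y = sprintf("%s quantiles", column),
                  title = sprintf("%s normality check", column)) +
    ggplot2::theme_minimal()
}
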