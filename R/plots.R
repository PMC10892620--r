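#' Observed-versus-predicted activity plot
#'
#' @param object A [fit_qsar()] model.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot qsar_fit
#' @export
autoplot.qsar_fit <- function(object, ...) {
  d <- augment(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[object$activity]], y = .data$.fitted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Observed activity", y = "Predicted activity",
                  title = sprintf("MLR fit (n = %d, p = %d)", object$n, object$p)) +
    ggplot2::theme_minimal()
}

#' Williams plot of the applicability domain
#'
#' Standardized residuals against leverages, with the warning leverage
#' `h*` (vertical) and the residual band (horizontal) drawn as dashed
#' lines. Flagged compounds are labelled.
#'
#' @param object An [assess_domain()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot qsar_domain
#' @export
autoplot.qsar_domain <- function(object, ...) {
  h_star <- attr(object, "h_star")
  band <- attr(object, "residual_band")
  d <- as_tibble(object)
  d$flagged <- d$high_leverage | d$residual_outlier
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$leverage, y = .data$std_residual)) +
    ggplot2::geom_vline(xintercept = h_star, linetype = "dashed", colour = "red3") +
    ggplot2::geom_hline(yintercept = c(-band, band), linetype = "dashed",
                        colour = "red3") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$flagged)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black", `TRUE` = "red3"),
                                 guide = "none") +
    ggplot2::labs(x = "Leverage h", y = "Standardized residual",
                  title = sprintf("Williams plot (h* = %.3f)", h_star)) +
    ggplot2::theme_minimal()
  if (any(d$flagged)) {
    p <- p + ggplot2::geom_text(
      data = d[d$flagged, ],
      ggplot2::aes(label = .data$compound_id),
      vjust = -0.8, size = 3
    )
  }
  p
}

#' Distribution of scrambled-model R2 values
#'
#' Histogram of the Y-randomization trial `r2` values with the original
#' model's `r2` marked.
#'
#' @param object A [y_randomization()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot qsar_yrand
#' @export
autoplot.qsar_yrand <- function(object, ...) {
  ggplot2::ggplot(object$trials, ggplot2::aes(x = .data$r2)) +
    ggplot2::geom_histogram(bins = 15, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$original["r2"],
                        colour = "red3", linewidth = 1) +
    ggplot2::labs(x = expression(R^2 ~ "of scrambled fits"), y = "Trials",
                  title = sprintf("Y-randomization (%d trials)", object$n_trials)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
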