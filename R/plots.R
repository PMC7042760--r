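# ggplot2 display methods for the main result types.

#' @method autoplot extinction_result
#' @export
autoplot.extinction_result <- function(object, ...) {
  ggplot2::ggplot(
    object$curve,
    ggplot2::aes(x = .data$fraction_removed, y = .data$fraction_surviving)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = paste0("Fraction of ", object$level_removed, "s removed"),
      y = "Fraction of other level surviving",
      title = sprintf(
        "Secondary-extinction curve (R = %.3f)", object$R
      )
    ) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' @method autoplot null_ensemble
#' @export
autoplot.null_ensemble <- function(object, ...) {
  ggplot2::ggplot(
    tibble::tibble(value = object$null_values),
    ggplot2::aes(x = .data$value)
  ) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "firebrick") +
    ggplot2::labs(
      x = object$metric_name, y = "Null draws",
      title = sprintf(
        "Observed vs fixed-marginal null (z = %.2f)", object$z
      )
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot lmm_fit
#' @export
autoplot.lmm_fit <- function(object, ...) {
  if (is.null(object$fit)) {
    abort("This fit carries no underlying model object to plot.")
  }
  data <- if (object$engine == "nlme") {
    object$fit$data
  } else {
    stats::model.frame(object$fit)
  }
  pred <- object$terms$term[object$terms$term != "(Intercept)"][1]
  ggplot2::ggplot(
    data,
    ggplot2::aes(x = .data[[pred]], y = .data[[object$response]])
  ) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(
      intercept = object$terms$estimate[object$terms$term == "(Intercept)"],
      slope = object$terms$estimate[object$terms$term == pred],
      colour = "firebrick"
    ) +
    ggplot2::labs(x = pred, y = object$response) +
    ggplot2::theme_minimal()
}

#' Gradient scatter plot of a per-walk metric against elevation
#'
#' @param metrics Per-walk metric table with `elevation` and the metric.
#' @param metric Metric column name.
#' @param colour Optional column mapped to point colour (e.g. `"lui"`).
#' @return A ggplot object.
#' @export
plot_gradient <- function(metrics, metric, colour = NULL) {
  p <- ggplot2::ggplot(
    metrics[is.finite(metrics[[metric]]), ],
    ggplot2::aes(x = .data$elevation, y = .data[[metric]])
  ) +
    ggplot2::geom_point(
      if (!is.null(colour)) ggplot2::aes(colour = .data[[colour]])
    ) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
      colour = "grey30"
    ) +
    ggplot2::labs(x = "Elevation (m a.s.l.)", y = metric) +
    ggplot2::theme_minimal()
  p
}
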