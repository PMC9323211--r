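#' Plot a release curve
#'
#' @param object A [release_curve()].
#' @param ... Unused.
#' @return A ggplot: mean cumulative release vs time with +/- SD ribbon.
#' @export
autoplot.release_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_min,
                                       y = .data$mean_release)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$mean_release - .data$sd_release,
      ymax = .data$mean_release + .data$sd_release), alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (min)",
                  y = paste0("Cumulative release (",
                             attr(object, "units"), ")"),
                  title = attr(object, "drug")) +
    ggplot2::theme_minimal()
}

#' Plot a fitted release model over its data
#'
#' @param fit A `release_fit`.
#' @param curve The [release_curve()] the model was fitted to.
#' @param n Number of prediction points.
#' @return A ggplot of data points and the fitted curve.
#' @export
plot_release_fit <- function(fit, curve, n = 400) {
  stopifnot(inherits(fit, "release_fit"))
  curve <- as_release_curve(curve)
  grid <- seq(min(curve$time_min), max(curve$time_min), length.out = n)
  pred <- tibble(time_min = grid,
                 mean_release = classical_release(fit$model_name, grid,
                                                  fit$params))
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$time_min,
                                      y = .data$mean_release)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_line(data = pred, colour = "#2166AC") +
    ggplot2::labs(x = "Time (min)", y = "Cumulative release",
                  title = sprintf("%s fit to %s (AICc %.1f)",
                                  fit$model_name, fit$drug, fit$aicc)) +
    ggplot2::theme_minimal()
}

#' Plot a Riccati regime sweep
#'
#' @param sweep A tibble from [riccati_sweep()].
#' @param part `"re"` or `"im"`: which component to plot.
#' @return A ggplot faceted by `(omega, r)`.
#' @export
plot_riccati_sweep <- function(sweep, part = c("re", "im")) {
  part <- match.arg(part)
  ycol <- if (part == "re") "re_z" else "im_z"
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$t, y = .data[[ycol]])) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(
      ggplot2::vars(.data$omega, .data$r), scales = "free",
      labeller = ggplot2::label_both) +
    ggplot2::labs(x = "t", y = paste0(toupper(substr(part, 1, 1)),
                                      substr(part, 2, 2), " z")) +
    ggplot2::theme_minimal()
}

#' Plot a fractality panel
#'
#' @param ordering A tibble from [drug_ordering()].
#' @return A ggplot bar chart of dimension by drug, in rank order.
#' @export
plot_fractality <- function(ordering) {
  ordering <- dplyr::mutate(
    ordering, drug = factor(.data$drug, levels = .data$drug))
  ggplot2::ggplot(ordering, ggplot2::aes(x = .data$drug,
                                         y = .data$dimension)) +
    ggplot2::geom_col(fill = "#4393C3") +
    ggplot2::coord_cartesian(
      ylim = c(1, max(1.05, max(ordering$dimension)))) +
    ggplot2::labs(x = NULL, y = "Fractality degree (fractal dimension)") +
    ggplot2::theme_minimal()
}
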