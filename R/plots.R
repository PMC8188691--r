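#' Plot a decay-model fit
#'
#' Observed rank abundances and the fitted power-law decay curve on log--log
#' axes.
#'
#' @param object A `decay_fit` from [fit_decay_model()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.decay_fit <- function(object, ...) {
  dat <- object$data
  curve <- tibble::tibble(
    rank = seq(min(dat$rank), max(dat$rank), length.out = 200),
    abundance = (object$scale * seq(min(dat$rank), max(dat$rank), length.out = 200))^(-object$exponent)
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$rank, y = .data$abundance)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = curve, colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "species rank", y = "relative abundance",
      title = sprintf(
        "abundance = (%.3g × rank)^-%.3g,  R² = %.3f",
        object$scale, object$exponent, object$r_squared
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-bin detection probabilities
#'
#' @param detection Tibble from [detection_probability()]; a `depth` or
#'   `condition` column, if present, is mapped to colour.
#' @return A ggplot object.
#' @export
plot_detection <- function(detection) {
  detection <- dplyr::mutate(
    detection,
    label = factor(.data$label, levels = rev(unique(.data$label)))
  )
  colour_var <- intersect(c("depth", "condition"), names(detection))[1]
  p <- ggplot2::ggplot(detection, ggplot2::aes(x = .data$label, y = .data$probability))
  p <- if (!is.na(colour_var)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = factor(.data[[colour_var]])), size = 2) +
      ggplot2::geom_line(ggplot2::aes(
        colour = factor(.data[[colour_var]]),
        group = factor(.data[[colour_var]])
      )) +
      ggplot2::labs(colour = colour_var)
  } else {
    p + ggplot2::geom_point(size = 2) + ggplot2::geom_line(ggplot2::aes(group = 1))
  }
  p +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(
      x = "expected relative abundance bin (rare → abundant)",
      y = "detection probability"
    ) +
    ggplot2::theme_minimal()
}

#' Plot precision (or recall) against sequencing depth
#'
#' @param results Metric tibble from [evaluate_run()] with a `depth` column.
#' @param metric Metric column to plot (default `"precision"`).
#' @return A ggplot object.
#' @export
plot_depth_trend <- function(results, metric = "precision") {
  ggplot2::ggplot(results, ggplot2::aes(
    x = .data$depth, y = .data[[metric]], colour = .data$group
  )) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE, linewidth = 0.5) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "sequencing depth (reads)", y = metric) +
    ggplot2::theme_minimal()
}
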