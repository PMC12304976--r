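#' Plot a response or sensitivity curve
#'
#' Doubly logarithmic level-response plot with gate-failing points shown as
#' crosses, plus 1/3-slope (or -2/3) and unit-slope (or flat) reference
#' guides.
#'
#' @param df Response-curve tibble (`level_pa`, `magnitude`, optional
#'   `passed`, `segment`, `freq`).
#' @param reference_slope Slope of the red reference guide (1/3 for response
#'   curves, -2/3 for sensitivity curves).
#' @return A ggplot object.
#' @export
plot_response_curve <- function(df, reference_slope = 1 / 3) {
  stopifnot(is.data.frame(df))
  if (!"passed" %in% names(df)) df$passed <- TRUE
  anchor <- df[which.max(df$magnitude), ]
  ref <- tibble::tibble(
    level_pa = range(df$level_pa),
    magnitude = anchor$magnitude *
      (range(df$level_pa) / anchor$level_pa)^reference_slope)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$level_pa,
                                        y = .data$magnitude)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$passed), size = 2) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 4),
                                name = "phase locked") +
    ggplot2::geom_line(data = ref, linetype = "dashed", colour = "red") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "stimulus pressure (Pa)", y = "response magnitude") +
    ggplot2::theme_minimal()
  if ("segment" %in% names(df) && length(unique(df$segment)) > 1)
    p <- p + ggplot2::facet_wrap(~segment)
  p
}

#' @export
autoplot.cohort_trend <- function(object, ...) {
  ggplot2::ggplot(object$minima,
                  ggplot2::aes(x = .data$freq, y = .data$min_slope)) +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$min_slope - .data$se,
                                        ymax = .data$min_slope + .data$se),
                           width = 0, colour = "steelblue") +
    ggplot2::geom_abline(slope = object$m, intercept = object$q,
                         colour = "red") +
    ggplot2::geom_hline(yintercept = 1 / 3, linetype = "dashed") +
    ggplot2::labs(x = "stimulus frequency (Hz)",
                  y = "minimum local slope",
                  title = sprintf("mean minimum slope %.3f (95%% CI %.2f-%.2f)",
                                  object$mean_min, object$ci95_mean[1],
                                  object$ci95_mean[2])) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.aligned_sensitivity <- function(object, ...) {
  ggplot2::ggplot(object$average,
                  ggplot2::aes(x = .data$x, y = .data$mean_log_s)) +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean_log_s - .data$sd_log_s,
      ymax = .data$mean_log_s + .data$sd_log_s), width = 0) +
    ggplot2::geom_abline(slope = -2 / 3, intercept = 0, colour = "red",
                         linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "log10 pressure re inflection",
                  y = "log10 sensitivity re inflection") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.dp_report <- function(object, ...) {
  ggplot2::ggplot(object$ratios,
                  ggplot2::aes(x = pa_to_db(.data$level_pa),
                               y = .data$ratio)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::labs(x = "primary level (dB SPL)",
                  y = "cubic DP / primary magnitude ratio") +
    ggplot2::theme_minimal()
}
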