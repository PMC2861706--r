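# ggplot2 visualizations for the result objects.

#' @rdname fit_calibration
#' @param object An `ipod_calibration` object.
#' @export
autoplot.ipod_calibration <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(.data$dilution, .data$signal)) +
    ggplot2::geom_line(
      ggplot2::aes(y = .data$fitted),
      linetype = 2, colour = "grey40"
    ) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$in_regime), size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "input dilution fraction", y = "corrected PCR signal",
      colour = "log-linear regime",
      title = sprintf("Calibration: slope %.2f, r² %.3f", object$slope, object$r2)
    )
}

#' @rdname assess_linearity
#' @param object An `ipod_linearity` object.
#' @export
autoplot.ipod_linearity <- function(object, ...) {
  gg <- ggplot2::ggplot(object$series, ggplot2::aes(.data$dose, .data$signal)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE, colour = "grey60") +
    ggplot2::labs(x = "UV dose (J/m²)", y = "signal")
  if (!is.na(object$breakpoint)) {
    gg <- gg +
      ggplot2::geom_vline(xintercept = object$breakpoint, linetype = 3) +
      ggplot2::labs(title = sprintf("Slope break at %.3g J/m²", object$breakpoint))
  } else {
    gg <- gg + ggplot2::labs(title = "Linear dose response")
  }
  gg
}

#' @rdname detect_phase_transition
#' @param object A `phase_transition` object.
#' @export
autoplot.phase_transition <- function(object, ...) {
  ggplot2::ggplot(
    object$excess,
    ggplot2::aes(.data$repeat_count, .data$excess_ratio)
  ) +
    ggplot2::geom_hline(yintercept = 1, colour = "grey60") +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = 3) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "telomeric repeats", y = "excess over linear baseline",
      title = if (is.na(object$onset_repeats)) {
        "No sustained excess over baseline"
      } else {
        sprintf(
          "Phase transition at %d repeats; plateau %.1f-fold",
          object$onset_repeats, object$plateau_fold
        )
      }
    )
}

#' Plot a repair time course
#'
#' @param course Data frame with columns `time_h`, `ip_over_input` and
#'   optionally `region`.
#' @return A ggplot.
#' @export
plot_repair_course <- function(course) {
  c_ <- as_tibble(course)
  aes <- if (is.null(c_$region)) {
    ggplot2::aes(.data$time_h, .data$ip_over_input)
  } else {
    ggplot2::aes(.data$time_h, .data$ip_over_input, colour = .data$region)
  }
  ggplot2::ggplot(c_, aes) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "time post-UV (h)", y = "IP / Input")
}

#' Plot a binned TRF lane profile
#'
#' @param lane A [bin_lane()] result.
#' @return A ggplot with fragment length (kb, log scale, decreasing along the
#'   lane) against interval intensity.
#' @export
plot_lane <- function(lane) {
  l <- as_tibble(lane)
  ggplot2::ggplot(l, ggplot2::aes(.data$length_bp / 1000, .data$od)) +
    ggplot2::geom_col(width = 0.01, just = 0) +
    ggplot2::geom_vline(xintercept = mean_trf(l), linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "fragment length (kb)", y = "interval OD",
      title = sprintf("Mean TRF %.2f kb", mean_trf(l))
    )
}
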