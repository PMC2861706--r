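# broom-style tidiers for the fitted objects.

#' @rdname fit_calibration
#' @param x An `ipod_calibration` object.
#' @param ... Unused.
#' @export
tidy.ipod_calibration <- function(x, ...) {
  x$points
}

#' @rdname fit_calibration
#' @export
glance.ipod_calibration <- function(x, ...) {
  tibble(
    slope = x$slope, intercept = x$intercept, r2 = x$r2,
    n_points = nrow(x$points), n_in_regime = sum(x$points$in_regime)
  )
}

#' @rdname assess_linearity
#' @param x An `ipod_linearity` object.
#' @param ... Unused.
#' @export
tidy.ipod_linearity <- function(x, ...) {
  x$series
}

#' @rdname assess_linearity
#' @export
glance.ipod_linearity <- function(x, ...) {
  tibble(
    slope = x$slope, breakpoint = x$breakpoint,
    slope_low = x$slope_low, slope_high = x$slope_high,
    rss_one_segment = x$rss1, rss_two_segment = x$rss2
  )
}

#' @rdname detect_phase_transition
#' @param x A `phase_transition` object.
#' @param ... Unused.
#' @export
tidy.phase_transition <- function(x, ...) {
  x$excess
}

#' @rdname detect_phase_transition
#' @export
glance.phase_transition <- function(x, ...) {
  tibble(
    onset_repeats = x$onset_repeats, plateau_fold = x$plateau_fold,
    threshold = x$threshold, equi_baseline_dev = x$equi_baseline_dev
  )
}

#' @rdname shortening_analysis
#' @param x A `trf_shortening` object.
#' @param ... Unused.
#' @export
tidy.trf_shortening <- function(x, ...) {
  dplyr::left_join(x$rates, x$dose_tests, by = "dose")
}

#' @rdname shortening_analysis
#' @export
glance.trf_shortening <- function(x, ...) {
  tibble(
    mean_rate_kb_per_passage = mean(x$rates$rate_kb_per_passage),
    n_doses = nrow(x$rates),
    n_significant = sum(x$dose_tests$significant, na.rm = TRUE)
  )
}
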