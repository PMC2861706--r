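# IPoD quantification: background correction, dilution calibration curves,
# IP/Input estimation, dose-response normalization, linearity assessment,
# fold-sensitivity and percent-repair arithmetic on densitometry tables.

#' Background-correct densitometry measurements
#'
#' Subtracts the per-measurement background from the raw intensity, flooring
#' at zero. Works on a measurement table and adds `corrected` and `clipped`
#' columns; `clipped` marks measurements whose background exceeded the signal.
#'
#' @param measurements A data frame with numeric columns `intensity` and
#'   `background` (both >= 0).
#' @return The input as a tibble with `corrected` and `clipped` added.
#' @export
correct_background <- function(measurements) {
  m <- as_tibble(measurements)
  if (is.null(m$intensity) || is.null(m$background)) {
    abort("`measurements` needs `intensity` and `background` columns.")
  }
  if (any(m$intensity < 0) || any(m$background < 0)) {
    abort("Raw intensities and backgrounds must be >= 0.")
  }
  m |>
    dplyr::mutate(
      corrected = pmax(.data$intensity - .data$background, 0),
      clipped = .data$background > .data$intensity
    )
}

#' Fit an input-dilution calibration curve
#'
#' Least-squares line of log(signal) on log(dilution). Quantitative PCR at a
#' fixed cycle number is only proportional to template over its log-linear
#' regime; points that have left that regime (saturation at the least-diluted
#' end) are detected by iterative top-down exclusion: while the least-diluted
#' remaining point falls short of a line fitted to the others by more than
#' `residual_threshold` (relative), it is flagged out-of-regime and dropped.
#' Only shortfalls count: saturation can only depress the signal below the
#' power law.
#'
#' @param dilutions Dilution fractions in (0, 1].
#' @param signals Background-corrected signals, same length.
#' @param residual_threshold Relative deviation above which the top point is
#'   excluded (default 0.15).
#' @return An object of class `ipod_calibration`: list with `points` (tibble:
#'   `dilution`, `signal`, `in_regime`, `fitted`), `slope`, `intercept` (log
#'   scale), `r2`, `signal_range` (of in-regime points).
#' @export
fit_calibration <- function(dilutions, signals, residual_threshold = 0.15) {
  if (length(dilutions) != length(signals)) abort("Lengths differ.")
  keep <- signals > 0
  if (sum(keep) < 3) abort("Calibration needs >= 3 points with positive signal.")
  pts <- tibble(dilution = dilutions[keep], signal = signals[keep]) |>
    dplyr::arrange(.data$dilution)
  in_regime <- rep(TRUE, nrow(pts))
  repeat {
    idx <- which(in_regime)
    if (length(idx) < 3) abort("Calibration failed: fewer than 3 in-regime points.")
    top <- idx[length(idx)]
    rest <- idx[-length(idx)]
    if (length(rest) < 2) break
    fit0 <- lm(log(signal) ~ log(dilution), data = pts[rest, ])
    pred_top <- exp(predict(fit0, newdata = pts[top, ]))
    # saturation always shows as a signal shortfall relative to the power law,
    # so only negative deviations mark the out-of-regime end
    rel <- (pts$signal[top] - pred_top) / pred_top
    if (rel < -residual_threshold) in_regime[top] <- FALSE else break
  }
  fit <- lm(log(signal) ~ log(dilution), data = pts[in_regime, ])
  pts$in_regime <- in_regime
  pts$fitted <- exp(predict(fit, newdata = pts))
  ls_ <- log(pts$signal[in_regime])
  tss <- sum((ls_ - mean(ls_))^2)
  r2 <- if (tss == 0) 1 else max(0, 1 - sum(resid(fit)^2) / tss)
  structure(
    list(
      points = pts,
      slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      r2 = r2,
      signal_range = range(pts$signal[in_regime])
    ),
    class = "ipod_calibration"
  )
}

#' @export
print.ipod_calibration <- function(x, ...) {
  cat(sprintf(
    "<ipod_calibration> %d/%d points in regime; slope %.3f, r2 %.4f\n",
    sum(x$points$in_regime), nrow(x$points), x$slope, x$r2
  ))
  invisible(x)
}

#' Estimate IP/Input from a calibration curve
#'
#' Inverts the fitted log-log line to find the input dilution whose signal
#' matches the (background-corrected) IP signal; that dilution fraction is the
#' IP/Input estimate. Signals outside the range spanned by the in-regime
#' calibration points are still inverted but flagged as extrapolations.
#'
#' @param ip_signal Numeric vector of corrected IP signals (>= 0).
#' @param curve An [fit_calibration()] object.
#' @return A tibble: `ip_signal`, `ip_over_input`, `extrapolated`.
#' @export
estimate_ip_over_input <- function(ip_signal, curve) {
  stopifnot(inherits(curve, "ipod_calibration"))
  if (any(ip_signal < 0)) abort("`ip_signal` must be >= 0.")
  est <- ifelse(
    ip_signal == 0, 0,
    exp((log(ip_signal) - curve$intercept) / curve$slope)
  )
  extra <- ip_signal != 0 &
    (ip_signal < curve$signal_range[1] | ip_signal > curve$signal_range[2])
  if (any(extra)) {
    warn(sprintf(
      "%d IP signal(s) outside the calibrated range; estimates are extrapolations.",
      sum(extra)
    ))
  }
  tibble(ip_signal = ip_signal, ip_over_input = est, extrapolated = extra)
}

#' Quantify IP/Input across a measurement table
#'
#' The workhorse over tables produced by gel densitometry (or by
#' [generate_gel_signals()]): for every group, fits a calibration curve on the
#' `input_dilution` rows and inverts it at the `IP` row's corrected signal.
#'
#' @param measurements Long table with columns `region`, `replicate`, `kind`
#'   (`"IP"` or `"input_dilution"`), `dilution` (for dilution rows),
#'   `intensity`, `background`, plus any of `dose`, `time_h`.
#' @param ... Grouping columns (tidy-select style bare names) in addition to
#'   `region` and `replicate`, e.g. `dose` or `time_h`.
#' @param residual_threshold Passed to [fit_calibration()].
#' @return A tibble with one row per group: grouping columns plus
#'   `ip_over_input` and `extrapolated`.
#' @export
quantify_ipod <- function(measurements, ..., residual_threshold = 0.15) {
  m <- correct_background(measurements)
  m |>
    dplyr::group_by(.data$region, .data$replicate, ...) |>
    dplyr::group_modify(function(g, key) {
      dil <- g[g$kind == "input_dilution", ]
      ip <- g[g$kind == "IP", ]
      if (nrow(ip) != 1) abort("Each group must contain exactly one IP row.")
      curve <- fit_calibration(dil$dilution, dil$corrected, residual_threshold)
      est <- estimate_ip_over_input(ip$corrected, curve)
      tibble(ip_over_input = est$ip_over_input, extrapolated = est$extrapolated)
    }) |>
    dplyr::ungroup()
}

#' Normalize a dose-response series between two anchor doses
#'
#' Maps the signal at `low_anchor` to 0% and at `high_anchor` to 100%:
#' `pct = 100 * (s(D) - s(low)) / (s(high) - s(low))`.
#'
#' @param series Data frame with columns `dose` and `signal` (doses unique).
#' @param low_anchor,high_anchor Anchor doses, both present in `series`.
#' @return The series as a tibble with a `percent` column added.
#' @export
normalize_dose_response <- function(series, low_anchor = 0, high_anchor = 20) {
  s <- as_tibble(series)
  if (anyDuplicated(s$dose)) abort("Doses must be unique; average replicates first.")
  if (!all(c(low_anchor, high_anchor) %in% s$dose)) {
    abort("Both anchor doses must be present in the series.")
  }
  lo <- s$signal[s$dose == low_anchor]
  hi <- s$signal[s$dose == high_anchor]
  if (hi <= lo) abort("High-anchor signal must exceed low-anchor signal.")
  s |>
    dplyr::arrange(.data$dose) |>
    dplyr::mutate(percent = 100 * (.data$signal - lo) / (hi - lo))
}

#' Assess dose-response linearity and locate a slope break
#'
#' Fits a single line and all two-segment continuous fits with the breakpoint
#' at each candidate dose, picking the breakpoint minimizing total residual
#' sum of squares. The breakpoint is reported only when the two-segment fit
#' beats the one-segment fit by more than `f_ratio` (ratio of residual sums of
#' squares); otherwise the series is declared linear.
#'
#' @param series Data frame with columns `dose` and `signal`, >= 4 doses.
#' @param candidate_breakpoints Doses to try as breakpoints; default all
#'   interior observed doses.
#' @param f_ratio One-segment/two-segment RSS ratio required to declare a
#'   break (default 4).
#' @return An object of class `ipod_linearity`: list with `slope` (one-segment
#'   slope), `breakpoint` (dose or `NA`), `slope_low`, `slope_high` (segment
#'   slopes when a break is found), `rss1`, `rss2`, `series`.
#' @export
assess_linearity <- function(series, candidate_breakpoints = NULL, f_ratio = 4) {
  s <- as_tibble(series) |> dplyr::arrange(.data$dose)
  if (nrow(s) < 4) abort("Linearity assessment needs >= 4 doses.")
  fit1 <- lm(signal ~ dose, data = s)
  rss1 <- sum(resid(fit1)^2)
  tss <- sum((s$signal - mean(s$signal))^2)
  cands <- candidate_breakpoints %||% s$dose[c(-1, -nrow(s))]
  cands <- cands[cands > min(s$dose) & cands < max(s$dose)]
  best <- NULL
  for (b in cands) {
    # continuous two-segment (broken-stick) fit hinged at b
    x1 <- pmin(s$dose, b)
    x2 <- pmax(s$dose - b, 0)
    fit2 <- lm(s$signal ~ x1 + x2)
    rss2 <- sum(resid(fit2)^2)
    if (is.null(best) || rss2 < best$rss2) {
      best <- list(b = b, rss2 = rss2, coefs = coef(fit2))
    }
  }
  flat_or_linear <- rss1 <= tss * 1e-12 ||
    is.null(best) || !(rss1 / max(best$rss2, .Machine$double.eps) > f_ratio)
  structure(
    list(
      slope = unname(coef(fit1)[2]),
      breakpoint = if (flat_or_linear) NA_real_ else best$b,
      slope_low = if (flat_or_linear) NA_real_ else unname(best$coefs[2]),
      slope_high = if (flat_or_linear) NA_real_ else unname(best$coefs[3]),
      rss1 = rss1,
      rss2 = if (is.null(best)) NA_real_ else best$rss2,
      series = s
    ),
    class = "ipod_linearity"
  )
}

#' @export
print.ipod_linearity <- function(x, ...) {
  if (is.na(x$breakpoint)) {
    cat(sprintf("<ipod_linearity> linear; slope %.4g\n", x$slope))
  } else {
    cat(sprintf(
      "<ipod_linearity> slope break at %.3g: %.4g below, %.4g above\n",
      x$breakpoint, x$slope_low, x$slope_high
    ))
  }
  invisible(x)
}

#' Fold sensitivity between two regions
#'
#' Ratio of IP/Input fractions, optionally corrected for the regions'
#' dipyrimidine-site frequencies (fold of per-site damage rates rather than
#' per-fragment pulldown).
#'
#' @param frac_a,frac_b IP/Input fractions (`frac_b > 0`).
#' @param freq_a,freq_b Optional dipyrimidine frequencies (sites/100 nt);
#'   either both or neither.
#' @return A tibble: `fold` (uncorrected) and `fold_corrected` (`NA` when no
#'   frequencies are given).
#' @export
fold_sensitivity <- function(frac_a, frac_b, freq_a = NULL, freq_b = NULL) {
  if (any(frac_b == 0)) abort("`frac_b` must be > 0; the fold is undefined.")
  if (xor(is.null(freq_a), is.null(freq_b))) {
    abort("Provide both `freq_a` and `freq_b`, or neither.")
  }
  fold <- frac_a / frac_b
  corrected <- if (is.null(freq_a)) {
    NA_real_
  } else {
    (frac_a / freq_a) / (frac_b / freq_b)
  }
  tibble(fold = fold, fold_corrected = corrected)
}

#' Percent of lesions removed at a time point
#'
#' `100 * (1 - frac(t) / frac(0))`, with `frac(t)` linearly interpolated
#' between measured times.
#'
#' @param course Data frame with columns `time_h` and `ip_over_input` (times
#'   sorted; `ip_over_input` at the earliest time > 0).
#' @param t Hours (vectorized), within the observed time range.
#' @return Percent removed at each `t`.
#' @export
percent_removed <- function(course, t) {
  s <- as_tibble(course) |> dplyr::arrange(.data$time_h)
  if (s$ip_over_input[1] <= 0) abort("IP/Input at the first time point must be > 0.")
  if (any(t < min(s$time_h) | t > max(s$time_h))) {
    abort("`t` must lie within the observed time range.")
  }
  frac_t <- approx(s$time_h, s$ip_over_input, xout = t)$y
  100 * (1 - frac_t / s$ip_over_input[1])
}

#' Welch's unequal-variance t test
#'
#' Two-tailed heteroscedastic t test (Welch-Satterthwaite degrees of freedom)
#' between two replicate groups, the test used throughout for comparing
#' triplicate densitometry values.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @return A tibble: `statistic`, `df`, `p_value`, `degenerate` (TRUE when
#'   both groups have zero variance, in which case the p value is 1 for
#'   identical means and 0 otherwise, by continuity).
#' @export
welch_t <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("Each group needs >= 2 values.")
  }
  va <- stats::var(group_a)
  vb <- stats::var(group_b)
  if (va == 0 && vb == 0) {
    same <- isTRUE(all.equal(mean(group_a), mean(group_b)))
    return(tibble(
      statistic = if (same) 0 else Inf, df = NA_real_,
      p_value = if (same) 1 else 0, degenerate = TRUE
    ))
  }
  ht <- t.test(group_a, group_b, var.equal = FALSE)
  tibble(
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    degenerate = FALSE
  )
}
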