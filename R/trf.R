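# Mean telomere restriction fragment (TRF) length from Southern-blot lane
# densitometry. A lane profile is divided into 75 intervals; with ODi the
# background-corrected intensity of interval i and Li its fragment length,
# the mean TRF length is sum(ODi) / sum(ODi / Li), the intensity-weighted
# harmonic-type mean that weights each fragment length by the number of
# molecules rather than by hybridization mass.

#' Marker ladder for lane-position to fragment-length mapping
#'
#' @param positions Lane coordinates of the ladder rungs, strictly increasing
#'   with migration distance.
#' @param lengths_bp Fragment length (bp) at each rung, strictly decreasing.
#' @return A tibble of class `marker_ladder`.
#' @export
marker_ladder <- function(positions, lengths_bp) {
  if (length(positions) < 2) abort("A ladder needs >= 2 rungs.")
  if (length(positions) != length(lengths_bp)) abort("Lengths differ.")
  o <- order(positions)
  positions <- positions[o]
  lengths_bp <- lengths_bp[o]
  if (any(diff(lengths_bp) >= 0)) {
    abort("Fragment lengths must strictly decrease with migration distance.")
  }
  structure(
    tibble(position = positions, length_bp = lengths_bp),
    class = c("marker_ladder", class(tibble()))
  )
}

#' Map lane positions to fragment lengths
#'
#' Piecewise-linear interpolation of log(length) against position (the
#' standard log-linear migration approximation for agarose gels). Positions
#' outside the ladder span are extrapolated from the nearest two rungs and
#' flagged with a warning.
#'
#' @param ladder A [marker_ladder()].
#' @param position Numeric vector of lane coordinates.
#' @return Fragment lengths in bp.
#' @export
map_position_to_length <- function(ladder, position) {
  stopifnot(inherits(ladder, "marker_ladder"))
  lp <- ladder$position
  ll <- log(ladder$length_bp)
  outside <- position < min(lp) | position > max(lp)
  if (any(outside)) {
    warn(sprintf("%d position(s) outside the ladder span; extrapolating.", sum(outside)))
  }
  n <- length(lp)
  interp <- approx(lp, ll, xout = position, rule = 1)$y
  lo <- position < lp[1]
  hi <- position > lp[n]
  slope_lo <- (ll[2] - ll[1]) / (lp[2] - lp[1])
  slope_hi <- (ll[n] - ll[n - 1]) / (lp[n] - lp[n - 1])
  interp[lo] <- ll[1] + slope_lo * (position[lo] - lp[1])
  interp[hi] <- ll[n] + slope_hi * (position[hi] - lp[n])
  exp(interp)
}

#' Bin a raw lane profile into equal intervals
#'
#' Sums raw intensity into `n_bins` equal-width bins in lane-position space,
#' subtracts a per-lane constant background, and maps each bin center to a
#' fragment length through the ladder.
#'
#' @param profile Data frame with columns `position` and `intensity` covering
#'   the region of interest.
#' @param ladder A [marker_ladder()].
#' @param n_bins Number of intervals (default 75).
#' @param background `"min"` (default: the minimum raw intensity of the lane,
#'   an estimate of the blank film level), `"none"`, or a numeric constant,
#'   subtracted per raw point before binning (floored at zero).
#' @return A tibble of class `lane_profile` with `n_bins` rows: `interval`,
#'   `od`, `length_bp`.
#' @export
bin_lane <- function(profile, ladder, n_bins = 75, background = "min") {
  p <- as_tibble(profile)
  if (nrow(p) < n_bins) abort("Profile has fewer points than requested bins.")
  bg <- if (identical(background, "min")) {
    min(p$intensity)
  } else if (identical(background, "none")) {
    0
  } else if (is.numeric(background)) {
    background
  } else {
    abort("`background` must be \"min\", \"none\" or a number.")
  }
  breaks <- seq(min(p$position), max(p$position), length.out = n_bins + 1)
  idx <- pmin(findInterval(p$position, breaks, rightmost.closed = TRUE), n_bins)
  od <- vapply(
    seq_len(n_bins),
    function(i) sum(pmax(p$intensity[idx == i] - bg, 0)),
    numeric(1)
  )
  centers <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  out <- tibble(
    interval = seq_len(n_bins),
    od = od,
    length_bp = map_position_to_length(ladder, centers)
  )
  class(out) <- c("lane_profile", class(out))
  out
}

#' Mean TRF length of a lane
#'
#' The intensity-weighted statistic `sum(ODi) / sum(ODi / Li)`, reported in
#' kb. Invariant to uniform intensity rescaling; equals the interval length
#' exactly for a single-interval (delta) lane; always lies between the
#' shortest and longest fragment lengths carrying signal.
#'
#' @param lane Data frame with columns `od` (>= 0, not all zero) and
#'   `length_bp` (> 0), typically from [bin_lane()].
#' @return Mean TRF length in kb.
#' @export
mean_trf <- function(lane) {
  l <- as_tibble(lane)
  if (any(l$length_bp <= 0)) abort("Fragment lengths must be > 0.")
  if (any(l$od < 0)) abort("Interval intensities must be >= 0.")
  if (sum(l$od) <= 0) abort("Mean TRF is undefined for an all-zero lane.")
  (sum(l$od) / sum(l$od / l$length_bp)) / 1000
}

#' Telomere-shortening analysis across passages and doses
#'
#' Per dose, fits the least-squares loss rate of mean TRF against passage;
#' the dose effect is assessed by Welch-testing final-passage mean TRF of each
#' dose against the unirradiated (dose 0) lanes.
#'
#' @param records Data frame with columns `lane_id`, `passage`, `dose`,
#'   `mean_trf` (kb), >= 2 passages per dose.
#' @return An object of class `trf_shortening`: list with `rates` (tibble:
#'   `dose`, `rate_kb_per_passage`), `dose_tests` (tibble: `dose`, `p_value`,
#'   `significant` at 0.05; `NA` rows when replication is insufficient),
#'   `records`.
#' @export
shortening_analysis <- function(records) {
  r <- as_tibble(records)
  rates <- r |>
    dplyr::group_by(.data$dose) |>
    dplyr::group_modify(function(g, key) {
      if (dplyr::n_distinct(g$passage) < 2) {
        abort("Loss rate needs >= 2 passages per dose.")
      }
      tibble(rate_kb_per_passage = unname(coef(lm(mean_trf ~ passage, data = g))[2]))
    }) |>
    dplyr::ungroup()
  final <- max(r$passage)
  ref <- r$mean_trf[r$passage == final & r$dose == 0]
  tests <- r |>
    dplyr::filter(.data$passage == final, .data$dose != 0) |>
    dplyr::group_by(.data$dose) |>
    dplyr::group_modify(function(g, key) {
      if (length(ref) < 2 || nrow(g) < 2) {
        return(tibble(p_value = NA_real_, significant = NA))
      }
      wt <- welch_t(g$mean_trf, ref)
      tibble(p_value = wt$p_value, significant = wt$p_value < 0.05)
    }) |>
    dplyr::ungroup()
  structure(
    list(rates = rates, dose_tests = tests, records = r),
    class = "trf_shortening"
  )
}

#' @export
print.trf_shortening <- function(x, ...) {
  cat("<trf_shortening>\n")
  cat("  loss rates (kb/passage):\n")
  for (i in seq_len(nrow(x$rates))) {
    cat(sprintf(
      "    dose %6g: %.3f\n",
      x$rates$dose[i], x$rates$rate_kb_per_passage[i]
    ))
  }
  sig <- x$dose_tests$significant
  cat(sprintf(
    "  dose effect at final passage: %d/%d doses significant\n",
    sum(sig, na.rm = TRUE), length(sig)
  ))
  invisible(x)
}

#' Expected cell-number ratio under a per-passage density deficit
#'
#' When every lineage is split at the same ratio each passage, a relative
#' density deficit compounds geometrically: after `n_passages` the treated
#' culture holds `(1 - density_deficit)^n_passages` as many cells, i.e. a
#' `1 / (1 - density_deficit)^n_passages`-fold difference. A 25% deficit over
#' 16 passages would give a ~100-fold difference in harvested DNA -- the
#' control arithmetic showing that equal DNA yields imply equal doubling
#' numbers.
#'
#' @param density_deficit Fractional reduction in density at confluence,
#'   in `[0, 1)`.
#' @param n_passages Number of passages.
#' @param split_ratio Split fraction at passage (context only; it cancels
#'   when equal across arms). Default 1/4.
#' @return A tibble: `surviving_fraction`, `fold_difference`.
#' @export
expected_density_ratio <- function(density_deficit, n_passages, split_ratio = 0.25) {
  if (density_deficit < 0 || density_deficit >= 1) {
    abort("`density_deficit` must lie in [0, 1).")
  }
  if (split_ratio <= 0 || split_ratio > 1) abort("`split_ratio` must lie in (0, 1].")
  frac <- (1 - density_deficit)^n_passages
  tibble(surviving_fraction = frac, fold_difference = 1 / frac)
}

#' Mean TRF per lane from raw profiles
#'
#' Bins every lane of a raw profile table ([bin_lane()]), computes its mean
#' TRF length and joins the lane metadata, yielding the records table that
#' [shortening_analysis()] consumes.
#'
#' @param profiles Data frame with columns `lane_id`, `position`, `intensity`.
#' @param ladder A [marker_ladder()].
#' @param meta Data frame with columns `lane_id`, `passage`, `dose`.
#' @inheritParams bin_lane
#' @return A tibble: `lane_id`, `passage`, `dose`, `mean_trf` (kb).
#' @export
trf_lane_table <- function(profiles, ladder, meta, n_bins = 75, background = "min") {
  as_tibble(profiles) |>
    dplyr::group_by(.data$lane_id) |>
    dplyr::group_modify(function(g, key) {
      tibble(mean_trf = mean_trf(bin_lane(g, ladder, n_bins, background)))
    }) |>
    dplyr::ungroup() |>
    dplyr::left_join(as_tibble(meta), by = "lane_id") |>
    dplyr::select("lane_id", "passage", "dose", "mean_trf")
}
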