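# Dot-blot quantification for the 102-mer oligo experiments: per-dose
# normalization to a reference oligo, dose-independence testing and pooling,
# the expected-linear baseline for repeat-length series, and detection of the
# phase transition in UV sensitivity of tandem telomeric repeats.

#' Per-dose signal ratios to a reference oligo
#'
#' Divides every corrected intensity by the reference oligo's intensity at the
#' same dose and replicate, so the reference maps to 1 everywhere. Ratios are
#' invariant to global exposure rescaling (different film exposures).
#'
#' @param grid Long table with columns `oligo`, `dose`, `replicate`,
#'   `intensity` and optionally `background` (default 0).
#' @param reference Name of the reference oligo (default `"Telomere"`).
#' @return A tibble: `oligo`, `dose`, `replicate`, `ratio`.
#' @export
ratio_to_reference <- function(grid, reference = "Telomere") {
  g <- as_tibble(grid)
  if (is.null(g$background)) g$background <- 0
  g <- correct_background(g)
  ref <- g |>
    dplyr::filter(.data$oligo == reference) |>
    dplyr::select("dose", "replicate", ref_signal = "corrected")
  if (nrow(ref) == 0) abort(sprintf("Reference oligo '%s' not in grid.", reference))
  if (any(ref$ref_signal <= 0)) abort("Reference intensity must be > 0 at every dose.")
  if (dplyr::n_distinct(g$dose) < 2) {
    warn("Single-dose grid: ratios computed, dose-averaging will be skipped.")
  }
  g |>
    dplyr::inner_join(ref, by = c("dose", "replicate")) |>
    dplyr::transmute(
      oligo = .data$oligo, dose = .data$dose, replicate = .data$replicate,
      ratio = .data$corrected / .data$ref_signal
    )
}

#' Test dose-independence of signal ratios and pool across doses
#'
#' For each oligo, Welch-tests the replicate ratios between doses; when no
#' dose dependence is detected at level `alpha` the ratios are pooled by
#' arithmetic mean across doses (the operation that justifies averaging the
#' normalized signals of different UV doses). Dose-dependent oligos keep their
#' pooled mean for reference but are flagged.
#'
#' @param ratios Output of [ratio_to_reference()].
#' @param alpha Significance level for the dose-dependence test (default 0.05).
#' @return A tibble with one row per oligo: `oligo`, `ratio` (pooled mean),
#'   `p_value` (`NA` when replication is insufficient to test),
#'   `dose_dependent`, `tested`.
#' @export
dose_independence_and_average <- function(ratios, alpha = 0.05) {
  r <- as_tibble(ratios)
  doses <- sort(unique(r$dose))
  r |>
    dplyr::group_by(.data$oligo) |>
    dplyr::group_modify(function(g, key) {
      pooled <- mean(g$ratio)
      can_test <- length(doses) >= 2 &&
        all(table(g$dose) >= 2) && dplyr::n_distinct(g$dose) >= 2
      if (!can_test) {
        warn("Insufficient replication to test dose-independence; pooling anyway.")
        return(tibble(
          ratio = pooled, p_value = NA_real_,
          dose_dependent = FALSE, tested = FALSE
        ))
      }
      a <- g$ratio[g$dose == doses[1]]
      b <- g$ratio[g$dose == doses[2]]
      wt <- welch_t(a, b)
      tibble(
        ratio = pooled, p_value = wt$p_value,
        dose_dependent = wt$p_value < alpha, tested = TRUE
      )
    }) |>
    dplyr::ungroup()
}

#' Expected linear baseline for a repeat-length series
#'
#' The trivial expectation for a series of oligos whose dipyrimidine-bearing
#' tract grows: CPD yield proportional to the number of target sites in the
#' tract, i.e. linear through the origin in tract length (the telomeric tract
#' carries 4 sites per 6-nt repeat). The proportionality constant is fixed by
#' assigning 1 to the shortest tract (`anchor`, default the 12-mer).
#'
#' @param lengths Dipyrimidine-tract lengths in nt (positive; multiples of 6
#'   for telomeric-repeat designs).
#' @param anchor Tract length whose baseline is set to 1 (default 12).
#' @return A tibble: `dipyr_region_length`, `sites` (tract site count),
#'   `baseline`.
#' @export
expected_linear_response <- function(lengths, anchor = 12) {
  if (any(lengths <= 0)) abort("Tract lengths must be positive.")
  sites <- 4 * lengths / 6
  anchor_sites <- 4 * anchor / 6
  tibble(
    dipyr_region_length = lengths,
    sites = sites,
    baseline = sites / anchor_sites
  )
}

#' Normalize series signals to the shortest tract
#'
#' Divides a series' signals by its own value at the shortest dipyrimidine
#' tract (the 12-mer), putting the telomeric-repeat and matched non-repeat
#' series on a common relative scale.
#'
#' @param series Data frame with columns `dipyr_region_length` and `signal`.
#' @param anchor Tract length to normalize at (default 12; must be present).
#' @return The series as a tibble with a `normalized` column added.
#' @export
normalize_series_to_shortest <- function(series, anchor = 12) {
  s <- as_tibble(series)
  if (!anchor %in% s$dipyr_region_length) {
    abort(sprintf("Series must contain the %d-mer anchor.", anchor))
  }
  ref <- s$signal[s$dipyr_region_length == anchor]
  if (length(ref) != 1) abort("Exactly one signal per tract length expected.")
  if (ref <= 0) abort("Anchor signal must be > 0.")
  dplyr::mutate(s, normalized = .data$signal / ref)
}

#' Detect a phase transition in UV sensitivity along a repeat series
#'
#' Computes the excess ratio `r(n) = telo_norm(n) / baseline(n)` of the
#' 12-mer-normalized telomeric-repeat series over the expected linear
#' baseline, and reports the smallest repeat count at which `r` exceeds
#' `threshold` and stays above it for every longer oligo (a sustained
#' super-linear excess, the operational signature of the phase transition).
#' The plateau fold is the mean excess over the two longest tracts.
#'
#' @param telo_norm Telomeric series normalized via
#'   [normalize_series_to_shortest()]: columns `dipyr_region_length`,
#'   `repeat_count`, `normalized`.
#' @param equi_norm Optional matched non-repeat series (same columns except
#'   `repeat_count`); its mean absolute deviation from the baseline is
#'   reported as a sanity figure, not used in detection.
#' @param threshold Sustained excess ratio required to call the onset
#'   (default 1.5).
#' @param plateau_n Number of longest tracts averaged for the plateau fold
#'   (default 2).
#' @return An object of class `phase_transition`: list with `onset_repeats`
#'   (`NA` if never exceeded), `plateau_fold`, `excess` (tibble with
#'   `dipyr_region_length`, `repeat_count`, `excess_ratio`),
#'   `equi_baseline_dev`.
#' @export
detect_phase_transition <- function(telo_norm, equi_norm = NULL,
                                    threshold = 1.5, plateau_n = 2) {
  s <- as_tibble(telo_norm) |> dplyr::arrange(.data$dipyr_region_length)
  if (nrow(s) < 5) abort("Phase-transition detection needs >= 5 tract lengths.")
  base <- expected_linear_response(s$dipyr_region_length)
  excess <- tibble(
    dipyr_region_length = s$dipyr_region_length,
    repeat_count = s$repeat_count,
    excess_ratio = s$normalized / base$baseline
  )
  above <- excess$excess_ratio > threshold
  sustained <- rev(cumprod(rev(above))) == 1
  onset <- if (any(sustained)) excess$repeat_count[which(sustained)[1]] else NA_integer_
  topk <- utils::tail(excess$excess_ratio, plateau_n)
  dev <- NA_real_
  if (!is.null(equi_norm)) {
    e <- as_tibble(equi_norm)
    eb <- expected_linear_response(e$dipyr_region_length)
    dev <- mean(abs(e$normalized / eb$baseline - 1))
  }
  structure(
    list(
      onset_repeats = onset,
      plateau_fold = mean(topk),
      excess = excess,
      equi_baseline_dev = dev,
      threshold = threshold
    ),
    class = "phase_transition"
  )
}

#' @export
print.phase_transition <- function(x, ...) {
  cat(sprintf(
    "<phase_transition> onset at %s repeats; plateau fold %.2f (threshold %.2f)\n",
    ifelse(is.na(x$onset_repeats), "none", x$onset_repeats),
    x$plateau_fold, x$threshold
  ))
  invisible(x)
}

#' Analyze a dot-blot grid end to end
#'
#' Convenience wrapper: per-dose ratios to the reference oligo
#' ([ratio_to_reference()]) followed by dose-independence testing and pooling
#' ([dose_independence_and_average()]).
#'
#' @inheritParams ratio_to_reference
#' @inheritParams dose_independence_and_average
#' @return The pooled-ratio tibble of [dose_independence_and_average()].
#' @export
analyze_dotblot_grid <- function(grid, reference = "Telomere", alpha = 0.05) {
  dose_independence_and_average(ratio_to_reference(grid, reference), alpha)
}

#' Analyze a repeat-length series end to end
#'
#' Averages replicate corrected intensities per oligo, normalizes the
#' telomeric-repeat and matched non-repeat series to their 12-mers and runs
#' [detect_phase_transition()].
#'
#' @param data Long table as emitted by [generate_dotblot()] for the series
#'   preset: columns `series` (`"Telo"`/`"Equi"`), `dipyr_region_length`,
#'   `repeat_count`, `replicate`, `intensity`, `background`.
#' @inheritParams detect_phase_transition
#' @return A `phase_transition` object.
#' @export
analyze_repeat_series <- function(data, threshold = 1.5, plateau_n = 2) {
  d <- correct_background(as_tibble(data))
  mean_series <- function(sub) {
    sub |>
      dplyr::group_by(.data$dipyr_region_length, .data$repeat_count) |>
      dplyr::summarise(signal = mean(.data$corrected), .groups = "drop") |>
      dplyr::arrange(.data$dipyr_region_length)
  }
  telo <- normalize_series_to_shortest(mean_series(d[d$series == "Telo", ]))
  equi <- normalize_series_to_shortest(mean_series(d[d$series == "Equi", ]))
  detect_phase_transition(telo, equi, threshold = threshold, plateau_n = plateau_n)
}
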