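toy_grid <- function(true_ratio = 0.2, noise = 0, seed = 1, doses = c(100, 500)) {
  set.seed(seed)
  lnoise <- function(n) {
    if (noise == 0) return(rep(1, n))
    sd <- sqrt(log(1 + noise^2))
    rlnorm(n, -sd^2 / 2, sd)
  }
  tidyr::expand_grid(
    oligo = c("Telomere", "Other"), dose = doses, replicate = 1:3
  ) |>
    dplyr::mutate(
      intensity = ifelse(oligo == "Telomere", 1000, 1000 * true_ratio) *
        lnoise(dplyr::n()),
      background = 0
    )
}

test_that("reference ratios are 1 for the reference and exposure-invariant", {
  g <- toy_grid()
  r <- ratio_to_reference(g, "Telomere")
  expect_true(all(r$ratio[r$oligo == "Telomere"] == 1))
  rescaled <- dplyr::mutate(g, intensity = intensity * ifelse(dose == 100, 3.7, 0.4))
  expect_equal(ratio_to_reference(rescaled, "Telomere")$ratio, r$ratio)
  expect_error(
    ratio_to_reference(dplyr::mutate(g, intensity = 0), "Telomere"),
    "must be > 0"
  )
  expect_warning(ratio_to_reference(toy_grid(doses = 100), "Telomere"), "Single-dose")
})

test_that("noisy grids recover the generating ratio", {
  r <- ratio_to_reference(toy_grid(true_ratio = 0.2, noise = 0.1, seed = 8), "Telomere")
  pooled <- dose_independence_and_average(r)
  est <- pooled$ratio[pooled$oligo == "Other"]
  expect_gt(est, 0.16)
  expect_lt(est, 0.24)
})

test_that("dose-dependence is flagged only when ratios truly differ across doses", {
  same <- tibble::tibble(
    oligo = "A", dose = rep(c(100, 500), each = 3), replicate = rep(1:3, 2),
    ratio = c(0.21, 0.20, 0.19, 0.20, 0.21, 0.19)
  )
  out <- dose_independence_and_average(same)
  expect_false(out$dose_dependent)
  expect_equal(out$ratio, 0.2)

  diff_ <- tibble::tibble(
    oligo = "A", dose = rep(c(100, 500), each = 3), replicate = rep(1:3, 2),
    ratio = c(0.2, 0.201, 0.199, 0.6, 0.601, 0.599)
  )
  out2 <- dose_independence_and_average(diff_)
  expect_true(out2$dose_dependent)

  thin <- tibble::tibble(oligo = "A", dose = c(100, 500), replicate = 1, ratio = c(0.2, 0.21))
  expect_warning(out3 <- dose_independence_and_average(thin), "Insufficient")
  expect_false(out3$tested)
})

test_that("the expected baseline is linear through the origin in tract site count", {
  base <- expected_linear_response(c(12, 24, 30, 36, 42, 48, 60))
  expect_equal(base$baseline[base$dipyr_region_length == 12], 1)
  expect_equal(
    base$baseline[base$dipyr_region_length == 60] /
      base$baseline[base$dipyr_region_length == 12], 5
  )
  expect_equal(base$baseline, base$sites / base$sites[1])
  expect_equal(base$baseline, base$dipyr_region_length / 12)
})

test_that("12-mer normalization anchors at 1 and ignores raw scale", {
  s <- tibble::tibble(dipyr_region_length = c(12, 24, 60), signal = c(10, 25, 80))
  n1 <- normalize_series_to_shortest(s)
  expect_equal(n1$normalized[n1$dipyr_region_length == 12], 1)
  n2 <- normalize_series_to_shortest(dplyr::mutate(s, signal = signal * 10))
  expect_equal(n2$normalized, n1$normalized)
  expect_error(normalize_series_to_shortest(dplyr::mutate(s, signal = c(0, 25, 80))))
  expect_error(normalize_series_to_shortest(s[-1, ]))
})

test_that("a baseline-following series shows no phase transition", {
  lengths <- c(12, 24, 30, 36, 42, 48, 60)
  telo <- tibble::tibble(
    dipyr_region_length = lengths,
    repeat_count = lengths / 6,
    normalized = lengths / 12
  )
  pt <- detect_phase_transition(telo)
  expect_true(is.na(pt$onset_repeats))
  expect_equal(pt$plateau_fold, 1)
})

test_that("the noiseless series preset yields onset 5 and plateau 4.5 exactly", {
  d <- generate_dotblot("fig4", noise = 0, seed = 2)
  pt <- analyze_repeat_series(d)
  expect_equal(pt$onset_repeats, 5L)
  expect_equal(pt$plateau_fold, 4.5)
  expect_equal(pt$equi_baseline_dev, 0, tolerance = 1e-12)
  expect_equal(
    pt$excess$excess_ratio,
    c(1, 1, 3, 3.75, 4.5, 4.5, 4.5),
    tolerance = 1e-10
  )
})

test_that("a monotone ramp crossing the threshold later moves the onset", {
  lengths <- c(12, 24, 30, 36, 42, 48, 60)
  reps <- lengths / 6
  r <- c(1, 1.2, 1.4, 1.8, 2.0, 2.2, 2.5) # crosses 1.5 at n = 6, stays above
  telo <- tibble::tibble(
    dipyr_region_length = lengths, repeat_count = reps,
    normalized = (lengths / 12) * r
  )
  expect_equal(detect_phase_transition(telo)$onset_repeats, 6)
})

test_that("excess ratios are invariant to the baseline proportionality constant", {
  d <- generate_dotblot("fig4", noise = 0, seed = 3)
  pt1 <- analyze_repeat_series(d)
  scaled <- dplyr::mutate(d, intensity = (intensity - background) * 5 + background)
  pt2 <- analyze_repeat_series(scaled)
  expect_equal(pt1$excess$excess_ratio, pt2$excess$excess_ratio, tolerance = 1e-10)
})
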