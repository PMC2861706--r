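test_that("background correction floors at zero and flags clipping", {
  m <- tibble::tibble(intensity = c(100, 20, 15), background = c(20, 20, 20))
  out <- correct_background(m)
  expect_equal(out$corrected, c(80, 0, 0))
  expect_equal(out$clipped, c(FALSE, FALSE, TRUE))
  expect_error(correct_background(tibble::tibble(intensity = -1, background = 0)))
})

test_that("calibration fitting recovers a pure power law exactly", {
  d <- 2^-(0:6)
  cal <- fit_calibration(d, 500 * d)
  expect_equal(cal$slope, 1)
  expect_equal(cal$r2, 1)
  expect_true(all(cal$points$in_regime))
  expect_error(fit_calibration(c(1, 0.5), c(10, 5)), ">= 3")
})

test_that("saturated calibration points are excluded top-down and the slope survives", {
  d <- 2^-(0:8)
  s <- 700 * pmin(d, 0.35) # PCR leaves the log-linear regime above d = 0.35
  cal <- fit_calibration(d, s)
  expect_equal(cal$points$in_regime[cal$points$dilution %in% c(1, 0.5)], c(FALSE, FALSE))
  expect_true(all(cal$points$in_regime[cal$points$dilution < 0.5]))
  expect_equal(cal$slope, 1, tolerance = 0.02)
})

test_that("IP/Input estimation inverts the calibration curve", {
  d <- 2^-(0:8)
  cal <- fit_calibration(d, 1000 * d)
  est <- estimate_ip_over_input(c(0, 140, 1000), cal)
  expect_equal(est$ip_over_input, c(0, 0.14, 1))
  expect_false(any(est$extrapolated))
  expect_warning(estimate_ip_over_input(2000, cal), "outside")
})

test_that("IP/Input recovery tolerates multiplicative noise", {
  set.seed(61)
  d <- 2^-(0:8)
  ests <- vapply(1:10, function(i) {
    noise <- function(n) rlnorm(n, -0.5 * log(1 + 0.05^2), sqrt(log(1 + 0.05^2)))
    cal <- fit_calibration(d, 1000 * d * noise(length(d)))
    estimate_ip_over_input(1000 * 0.14 * noise(1), cal)$ip_over_input
  }, numeric(1))
  expect_lt(abs(mean(ests) - 0.14), 0.02)
})

test_that("dose-response normalization anchors 0% and 100% and is linear in between", {
  s <- tibble::tibble(dose = c(0, 10, 20, 30), signal = c(5, 10, 15, 18))
  out <- normalize_dose_response(s, 0, 20)
  expect_equal(out$percent[out$dose == 0], 0)
  expect_equal(out$percent[out$dose == 20], 100)
  expect_equal(out$percent[out$dose == 10], 50)
  expect_error(
    normalize_dose_response(tibble::tibble(dose = c(0, 20), signal = c(5, 5)), 0, 20)
  )
})

test_that("linearity assessment distinguishes linear, flat and saturating series", {
  lin <- assess_linearity(tibble::tibble(dose = 0:6 * 5, signal = 2 + 3 * (0:6 * 5)))
  expect_true(is.na(lin$breakpoint))
  expect_equal(lin$slope, 3)

  flat <- assess_linearity(tibble::tibble(dose = 0:5 * 10, signal = rep(4, 6)))
  expect_true(is.na(flat$breakpoint))
  expect_equal(flat$slope, 0)

  # closed-form pulldown saturates; curvature becomes visible near 30 J/m^2
  kw <- calibrate_yield(0.14, 20, 250)
  doses <- seq(0, 60, by = 5)
  sat <- assess_linearity(tibble::tibble(dose = doses, signal = 1 - exp(-kw * 250 * doses)))
  expect_false(is.na(sat$breakpoint))
  expect_lt(abs(sat$breakpoint - 30), 10)
  expect_lt(sat$slope_high, sat$slope_low)
  expect_error(assess_linearity(tibble::tibble(dose = c(0, 10, 20), signal = 1:3)))
})

test_that("fold sensitivity reproduces the 7-fold worked example and its correction", {
  f <- fold_sensitivity(0.14, 0.02)
  expect_equal(f$fold, 7)
  fc <- fold_sensitivity(0.14, 0.02, 33.3, 29.5)
  expect_equal(fc$fold_corrected, 6.2, tolerance = 0.01)
  # correction leaves the conclusion intact (same order of magnitude, ~7)
  expect_lt(abs(fc$fold_corrected - fc$fold) / fc$fold, 0.15)
  # scale invariance and identity
  expect_equal(fold_sensitivity(0.014, 0.002)$fold, 7)
  expect_equal(fold_sensitivity(0.3, 0.3, 10, 10)$fold_corrected, 1)
  expect_error(fold_sensitivity(0.1, 0))
})

test_that("percent removed interpolates linearly and is scale-invariant", {
  course <- tibble::tibble(time_h = c(0, 24, 48), ip_over_input = c(0.10, 0.06, 0.03))
  expect_equal(percent_removed(course, 48), 70)
  expect_equal(percent_removed(course, 36), 100 * (1 - 0.045 / 0.10))
  expect_equal(percent_removed(course, 0), 0)
  scaled <- dplyr::mutate(course, ip_over_input = ip_over_input * 13)
  expect_equal(percent_removed(scaled, c(12, 36, 48)), percent_removed(course, c(12, 36, 48)))
  flat <- tibble::tibble(time_h = c(0, 48), ip_over_input = c(0.2, 0.2))
  expect_equal(percent_removed(flat, c(0, 20, 48)), c(0, 0, 0))
  gone <- tibble::tibble(time_h = c(0, 48), ip_over_input = c(0.2, 0))
  expect_equal(percent_removed(gone, 48), 100)
  expect_error(percent_removed(course, 60), "within")
})

test_that("Welch's t matches a frozen worked example and behaves at the extremes", {
  # frozen from an independent computation of the classic two-sample example
  a <- c(27.5, 21.0, 19.0, 23.6, 17.0, 17.9, 16.9, 20.1, 21.9, 22.6, 23.1,
         19.6, 19.0, 21.7, 21.4)
  b <- c(27.1, 22.0, 20.8, 23.4, 23.4, 23.5, 25.8, 22.0, 24.8, 20.2, 21.9,
         22.1, 22.9, 30.5)
  wt <- welch_t(a, b)
  expect_equal(wt$statistic, -2.7078, tolerance = 1e-4)
  expect_equal(wt$df, 26.9527, tolerance = 1e-4)
  expect_equal(wt$p_value, 0.011616, tolerance = 1e-4)

  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_lt(welch_t(c(0, 0, 0), c(1, 1, 1.0001))$p_value, 0.001)
  expect_true(welch_t(c(2, 2), c(2, 2))$degenerate)
  expect_error(welch_t(1, c(1, 2)))
})

test_that("quantify_ipod recovers noiseless generator truth exactly", {
  g <- generate_gel_signals("fig2", noise = 0, seed = 4)
  q <- quantify_ipod(g, dose)
  truth <- attr(g, "truth")
  joined <- dplyr::left_join(q, truth, by = c("region", "dose"))
  expect_equal(joined$ip_over_input, joined$true_ip_over_input, tolerance = 1e-10)
  expect_false(any(joined$extrapolated))
})
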