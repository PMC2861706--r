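telomere_pool <- function(n, cfg, seed = NULL) {
  fragmentize(
    n, 1 / 3,
    strand_site_split = c(top = 0.25, bottom = 0.75),
    config = cfg, region_name = "telomere", seed = seed
  )
}

test_that("zero dose produces no lesions and negative dose is rejected", {
  cfg <- simulation_config(1e-4, seed = 5)
  lm0 <- simulate_cpd(build_telomere_repeat(3), 0, cfg)
  expect_equal(sum(lm0$lesion), 0)
  expect_error(simulate_cpd(build_telomere_repeat(3), -1, cfg))
  expect_equal(expected_cpd_per_molecule(build_telomere_repeat(3), 0, cfg), 0)
})

test_that("seeded lesion simulation is reproducible", {
  cfg <- simulation_config(2e-3, seed = 77)
  a <- simulate_cpd(build_telomere_repeat(20), 15, cfg)
  b <- simulate_cpd(build_telomere_repeat(20), 15, cfg)
  expect_identical(a$lesion, b$lesion)
})

test_that("Monte Carlo lesion counts match the closed-form mean for single repeats", {
  # per-site k*w*D = 0.01 on a one-repeat telomere (4 sites):
  # expected lesions/molecule = 4 * (1 - exp(-0.01))
  cfg <- simulation_config(0.01, seed = 303)
  pool <- tibble::tibble(
    fragment = 1:100000, length_bp = 6, sites = 4L,
    sites_top = 1L, sites_bottom = 3L
  )
  attr(pool, "region_name") <- "telomere"
  pool <- irradiate_pool(pool, 1, cfg)
  truth <- 4 * (1 - exp(-0.01))
  se <- sqrt(truth / nrow(pool)) # Poisson-binomial scale
  expect_lt(abs(mean(pool$lesions) - truth), 3 * se)
})

test_that("expected CPD per molecule is monotone in dose and inverts the calibration anchor", {
  # calibrated so a 40-site telomeric 102-mer carries 0.5 CPD at 500 J/m^2
  kw <- -log(1 - 0.5 / 40) / 500
  expect_equal(kw, 2.5157e-5, tolerance = 1e-4)
  cfg <- simulation_config(kw)
  oligo <- assemble_oligo("Telomere")
  expect_equal(expected_cpd_per_molecule(oligo, 500, cfg), 0.5)
  doses <- seq(0, 600, by = 50)
  e <- vapply(doses, function(d) expected_cpd_per_molecule(oligo, d, cfg), numeric(1))
  expect_true(all(diff(e) > 0))
  # linear limit: doubling a small dose doubles the expectation to < 1%
  e1 <- expected_cpd_per_molecule(oligo, 0.01, cfg)
  e2 <- expected_cpd_per_molecule(oligo, 0.02, cfg)
  expect_lt(abs(e2 / e1 - 2), 0.01)
})

test_that("fragment pools have uniform lengths and sequence-derived site counts", {
  cfg <- simulation_config(0, seed = 9)
  pool <- telomere_pool(20000, cfg, seed = 9)
  expect_true(all(pool$length_bp >= 500 & pool$length_bp <= 1000))
  se <- (1000 - 500) / sqrt(12) / sqrt(nrow(pool))
  expect_lt(abs(mean(pool$length_bp) - 750), 3 * se)
  # a 750 bp telomeric fragment carries 750 * (4/12) = 250 sites
  expect_equal(round(750 * (1 / 3)), 250)
  expect_true(all(abs(pool$sites - pool$length_bp / 3) <= 0.5))
  expect_equal(nrow(fragmentize(0, 1 / 3, config = cfg)), 0)
  expect_error(fragmentize(10, 1 / 3, length_range = c(1000, 500), config = cfg))
})

test_that("pulldown fraction matches its closed form and reproduces the 14% preset", {
  kw <- calibrate_yield(0.14, 20, 250)
  cfg <- simulation_config(kw, seed = 41)
  pool <- telomere_pool(1e5, cfg, seed = 41)
  pool <- irradiate_pool(pool, 20, cfg, seed = NULL)
  mc <- pulldown_fraction(pool)
  cf <- expected_pulldown_fraction(pool, 20, cfg)
  se <- sqrt(cf * (1 - cf) / nrow(pool))
  expect_lt(abs(mc - cf), 3 * se)
  expect_equal(mc, 0.14, tolerance = 0.05)
  # zero-dose pool pulls down nothing
  cold <- irradiate_pool(pool, 0, cfg, seed = NULL)
  expect_equal(pulldown_fraction(cold), 0)
  expect_error(pulldown_fraction(pool[0, ]))
})

test_that("strand-restricted pulldown respects the 3:1 telomeric site asymmetry", {
  kw <- 1e-6 # low dose regime
  cfg <- simulation_config(kw, seed = 12)
  pool <- telomere_pool(2e5, cfg, seed = 12)
  pool <- irradiate_pool(pool, 20, cfg, seed = NULL)
  bot <- strand_restricted_pulldown(pool, "bottom")
  top <- strand_restricted_pulldown(pool, "top")
  both <- pulldown_fraction(pool)
  expect_lte(bot, both)
  expect_lte(top, both)
  expect_equal(bot / top, 3, tolerance = 0.25)
  expect_equal((bot + top) / both, 1, tolerance = 0.05) # low-dose additivity
  # closed forms agree too
  expect_equal(
    expected_pulldown_fraction(pool, 20, cfg, "bottom") /
      expected_pulldown_fraction(pool, 20, cfg, "top"),
    3,
    tolerance = 0.01
  )
  # a strand without sites is never pulled down
  nosite <- pool
  nosite$sites_top <- 0L
  nosite <- irradiate_pool(nosite, 20, cfg, seed = NULL)
  expect_equal(strand_restricted_pulldown(nosite, "top"), 0)
})

test_that("repair kinetics follow the exponential-removal closed form", {
  flat <- simulate_repair(0.05, c(0, 12, 48), repair_model(c(x = 0)), "x")
  expect_equal(flat$removed_percent, c(0, 0, 0))
  # rate chosen so 70% is removed at 48 h
  rho <- -log(0.30) / 48
  expect_equal(rho, 0.02509, tolerance = 1e-3)
  course <- simulate_repair(0.01, c(0, 24, 48), repair_model(c(p53 = rho)), "p53")
  expect_equal(course$removed_percent[3], 70)
  expect_equal(course$removed_percent[2], 100 * (1 - exp(-0.6022)), tolerance = 1e-3)
  expect_true(all(diff(course$removed_percent) > 0))
  expect_error(simulate_repair(0.01, c(-1, 5), repair_model(c(p53 = rho)), "p53"))
  # dilution-only removal is region-independent
  dil <- repair_model(c(p53 = 0), dilution_rate = 0.01)
  a <- simulate_repair(0.02, c(0, 48), dil, "p53")
  b <- simulate_repair(0.10, c(0, 48), dil, "unlisted_region")
  expect_equal(a$removed_percent, b$removed_percent)
})

test_that("yield calibration inverts the pulldown model and is self-consistent", {
  expect_equal(calibrate_yield(0.14, 20, 250), 3.02e-5, tolerance = 1e-3)
  kw_p53 <- calibrate_yield(0.02, 20, 221)
  expect_equal(kw_p53, 4.57e-6, tolerance = 1e-3)
  # implied per-site sensitivity ratio behind a 7-fold pulldown difference
  expect_equal(calibrate_yield(0.14, 20, 250) / kw_p53, 6.6, tolerance = 0.01)
  # round trip: simulated pulldown at the calibrated yield recovers the target
  cfg <- simulation_config(calibrate_yield(0.14, 20, 250), seed = 88)
  pool <- telomere_pool(1e5, cfg, seed = 88)
  pool <- irradiate_pool(pool, 20, cfg, seed = NULL)
  expect_equal(pulldown_fraction(pool), 0.14, tolerance = 0.03)
  expect_error(calibrate_yield(0, 20, 250))
  expect_error(calibrate_yield(1, 20, 250))
})
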