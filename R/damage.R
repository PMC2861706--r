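# CPD induction / fragmentation / pulldown simulator.
#
# Model: a UV dose D (J/m^2) converts each dipyrimidine site independently
# into a cyclobutane pyrimidine dimer with probability
#   p = 1 - exp(-k * w_region * w_strand * D),
# where k is the per-site yield coefficient and the w are multiplicative
# sensitivity weights. Lesions are independent Bernoulli draws per site;
# cooperative multi-dimer formation is deliberately not modeled, so all
# sequence-context sensitivity enters through the weights. Only CPD are
# modeled (the antibody in the assay this emulates detects CPD, not 6-4
# photoproducts). For a fragment carrying m sites the probability of at least
# one lesion is then exactly 1 - exp(-m k w D), which is the closed form the
# Monte Carlo routines are checked against.

#' Simulation configuration for CPD induction
#'
#' @param yield_coeff Per-site CPD yield coefficient k, per (J/m^2); lesion
#'   probability per site is `1 - exp(-k * w * dose)`.
#' @param region_weights Named numeric vector of multiplicative region
#'   sensitivities; regions not named get weight 1.
#' @param strand_weights Named numeric vector `c(top = , bottom = )` of strand
#'   multipliers; default both 1.
#' @param seed Integer seed; stochastic operations seed their generator from
#'   this by default, so single-call runs are reproducible. Multi-step
#'   pipelines that seed once at the top should pass `seed = NULL` to the
#'   individual steps to draw from the ambient RNG stream in call order.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(yield_coeff,
                              region_weights = numeric(),
                              strand_weights = c(top = 1, bottom = 1),
                              seed = 1L) {
  if (yield_coeff < 0) abort("`yield_coeff` must be >= 0.")
  if (any(region_weights < 0) || any(strand_weights < 0)) {
    abort("Sensitivity weights must be >= 0.")
  }
  if (!all(c("top", "bottom") %in% names(strand_weights))) {
    abort("`strand_weights` must name both 'top' and 'bottom'.")
  }
  structure(
    list(
      yield_coeff = yield_coeff,
      region_weights = region_weights,
      strand_weights = strand_weights[c("top", "bottom")],
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

region_weight <- function(config, region_name) {
  w <- config$region_weights
  if (!is.null(w) && region_name %in% names(w)) unname(w[[region_name]]) else 1
}

site_probs <- function(region, dose, config) {
  sites <- enumerate_dipyr_sites(region)
  wr <- region_weight(config, region$name)
  ws <- unname(config$strand_weights[sites$strand])
  p <- 1 - exp(-config$yield_coeff * wr * ws * dose)
  list(sites = sites, p = p)
}

#' Simulate CPD formation on a duplex region
#'
#' Draws an independent Bernoulli lesion at every dipyrimidine site with
#' probability `1 - exp(-k * w_region * w_strand * dose)`.
#'
#' @param region A [duplex_region()].
#' @param dose UV dose in J/m^2 (>= 0).
#' @param config A [simulation_config()].
#' @param seed Seed for the draws; `NULL` draws from the ambient RNG stream.
#' @return A tibble (`lesion_map`) with one row per dipyrimidine site:
#'   `strand`, `start`, `dinucleotide`, `p` (per-site lesion probability) and
#'   `lesion` (logical); the dose is stored in attribute `"dose"`.
#' @export
simulate_cpd <- function(region, dose, config, seed = config$seed) {
  if (dose < 0) abort("`dose` must be >= 0.")
  sp <- site_probs(region, dose, config)
  if (!is.null(seed)) set.seed(seed)
  out <- sp$sites
  out$p <- sp$p
  out$lesion <- runif(nrow(out)) < sp$p
  attr(out, "dose") <- dose
  class(out) <- c("lesion_map", class(out))
  out
}

#' Expected CPD count per molecule
#'
#' Sum of per-site lesion probabilities over all dipyrimidine sites of the
#' duplex; for uniform weights this equals
#' `site_count * (1 - exp(-k * w * dose))`.
#'
#' @inheritParams simulate_cpd
#' @return Expected number of CPD per molecule (scalar).
#' @export
expected_cpd_per_molecule <- function(region, dose, config) {
  if (dose < 0) abort("`dose` must be >= 0.")
  sp <- site_probs(region, dose, config)
  sum(sp$p)
}

#' Simulate sonication into a fragment pool
#'
#' Fragment lengths are drawn i.i.d. uniform on `length_range` (the size range
#' sonication produces). For long tandem repeats and other compositionally
#' uniform regions the dipyrimidine content of a fragment is proportional to
#' its length, so per-fragment site counts are `round(length * sites_per_bp)`,
#' split between strands by `strand_site_split`.
#'
#' @param n_fragments Number of fragments to draw.
#' @param sites_per_bp Dipyrimidine sites per base pair of fragment (e.g. the
#'   telomeric repeat carries 4 sites per 12 bp of repeat, 1/3 per bp).
#' @param length_range Fragment length range in bp, default `c(500, 1000)`.
#' @param strand_site_split Named fractions `c(top = , bottom = )` of sites on
#'   each strand (telomere: 1/4 on the G-rich top, 3/4 on the C-rich bottom).
#' @param config A [simulation_config()] (supplies the default seed).
#' @param region_name Region label attached to the pool.
#' @param seed Seed for the draws; `NULL` draws from the ambient RNG stream.
#' @return A tibble (`fragment_pool`): `fragment`, `length_bp`, `sites`,
#'   `sites_top`, `sites_bottom`.
#' @export
fragmentize <- function(n_fragments,
                        sites_per_bp,
                        length_range = c(500, 1000),
                        strand_site_split = c(top = 0.5, bottom = 0.5),
                        config = simulation_config(0),
                        region_name = "region",
                        seed = config$seed) {
  if (length_range[1] > length_range[2]) abort("`length_range` must be increasing.")
  if (n_fragments == 0) {
    out <- tibble(
      fragment = integer(), length_bp = numeric(), sites = integer(),
      sites_top = integer(), sites_bottom = integer()
    )
  } else {
    if (!is.null(seed)) set.seed(seed)
    len <- runif(n_fragments, length_range[1], length_range[2])
    sites <- as.integer(round(len * sites_per_bp))
    top <- as.integer(round(sites * strand_site_split[["top"]]))
    out <- tibble(
      fragment = seq_len(n_fragments),
      length_bp = len,
      sites = sites,
      sites_top = top,
      sites_bottom = sites - top
    )
  }
  attr(out, "region_name") <- region_name
  class(out) <- c("fragment_pool", class(out))
  out
}

#' Assign lesions to a fragment pool
#'
#' Per-fragment lesion counts are binomial draws over the fragment's sites on
#' each strand at the per-site probability implied by `config` and `dose`.
#'
#' @param pool A [fragmentize()] pool.
#' @param dose UV dose in J/m^2.
#' @param config A [simulation_config()].
#' @param seed Seed for the draws; `NULL` draws from the ambient RNG stream.
#' @return The pool with added columns `lesions_top`, `lesions_bottom`,
#'   `lesions`; the dose is stored in attribute `"dose"`.
#' @export
irradiate_pool <- function(pool, dose, config, seed = config$seed) {
  if (dose < 0) abort("`dose` must be >= 0.")
  wr <- region_weight(config, attr(pool, "region_name") %||% "region")
  p_top <- 1 - exp(-config$yield_coeff * wr * config$strand_weights[["top"]] * dose)
  p_bot <- 1 - exp(-config$yield_coeff * wr * config$strand_weights[["bottom"]] * dose)
  if (!is.null(seed)) set.seed(seed)
  pool$lesions_top <- rbinom(nrow(pool), pool$sites_top, p_top)
  pool$lesions_bottom <- rbinom(nrow(pool), pool$sites_bottom, p_bot)
  pool$lesions <- pool$lesions_top + pool$lesions_bottom
  attr(pool, "dose") <- dose
  pool
}

#' Fraction of fragments recovered by the anti-CPD pulldown
#'
#' A fragment is pulled down if it carries at least one lesion on either
#' strand (the antibody is in molar excess, so recovery of a damaged fragment
#' is taken as certain). The matching closed form is
#' [expected_pulldown_fraction()].
#'
#' @param pool An [irradiate_pool()] result.
#' @return Fraction in `[0, 1]`.
#' @export
pulldown_fraction <- function(pool) {
  if (nrow(pool) == 0) abort("Pulldown fraction is undefined for an empty pool.")
  if (is.null(pool$lesions)) abort("Pool has no lesion assignment; run irradiate_pool().")
  mean(pool$lesions >= 1)
}

#' Strand-restricted pulldown fraction
#'
#' As [pulldown_fraction()], but a fragment counts as damaged only if it
#' carries a lesion on the named strand. Emulates strand-specific
#' amplification of the pulldown.
#'
#' @inheritParams pulldown_fraction
#' @param strand `"top"` or `"bottom"`.
#' @export
strand_restricted_pulldown <- function(pool, strand = c("top", "bottom")) {
  strand <- match.arg(strand)
  if (nrow(pool) == 0) abort("Pulldown fraction is undefined for an empty pool.")
  col <- paste0("lesions_", strand)
  if (is.null(pool[[col]])) abort("Pool has no lesion assignment; run irradiate_pool().")
  mean(pool[[col]] >= 1)
}

#' Closed-form expected pulldown fraction
#'
#' `1 - E[exp(-m * k * w * dose)]`, the expectation taken over the per-strand
#' site counts `m` of the fragments in the pool. Restricting to one strand
#' uses that strand's site counts and weight only.
#'
#' @inheritParams irradiate_pool
#' @param strand `NULL` (both strands) or `"top"`/`"bottom"`.
#' @return Expected fraction of fragments carrying at least one lesion.
#' @export
expected_pulldown_fraction <- function(pool, dose, config, strand = NULL) {
  if (nrow(pool) == 0) abort("Expected fraction is undefined for an empty pool.")
  wr <- region_weight(config, attr(pool, "region_name") %||% "region")
  k <- config$yield_coeff * wr
  ws <- config$strand_weights
  if (is.null(strand)) {
    expo <- k * (ws[["top"]] * pool$sites_top + ws[["bottom"]] * pool$sites_bottom) * dose
  } else {
    strand <- match.arg(strand, c("top", "bottom"))
    expo <- k * ws[[strand]] * pool[[paste0("sites_", strand)]] * dose
  }
  mean(1 - exp(-expo))
}

#' Excision-repair kinetics model
#'
#' Remaining lesion level decays as `exp(-(rate_region + dilution_rate) * t)`.
#' The dilution rate models loss of signal through replication of undamaged
#' strands rather than true repair; with dilution as the only mechanism all
#' regions decay identically, which is what makes a repair-incompetent region
#' (e.g. mitochondrial DNA) a usable negative control.
#'
#' @param region_rates Named numeric vector of removal rates (per hour).
#' @param dilution_rate Replication dilution rate (per hour), default 0.
#' @return An object of class `repair_model`.
#' @export
repair_model <- function(region_rates, dilution_rate = 0) {
  if (any(region_rates < 0) || dilution_rate < 0) abort("Rates must be >= 0.")
  structure(
    list(region_rates = region_rates, dilution_rate = dilution_rate),
    class = "repair_model"
  )
}

#' Simulate a post-UV repair time course
#'
#' @param initial Initial expected lesion level (e.g. IP/Input fraction at
#'   time 0).
#' @param times Hours post-irradiation, sorted, >= 0.
#' @param repair A [repair_model()].
#' @param region Region name (selects the rate; unknown names get rate 0).
#' @return A tibble (`repair_time_course`): `region`, `time_h`,
#'   `ip_over_input`, `removed_percent`.
#' @export
simulate_repair <- function(initial, times, repair, region) {
  if (any(times < 0)) abort("`times` must be >= 0.")
  if (is.unsorted(times)) abort("`times` must be sorted increasing.")
  rate <- if (region %in% names(repair$region_rates)) {
    repair$region_rates[[region]]
  } else {
    0
  }
  remaining <- initial * exp(-(rate + repair$dilution_rate) * times)
  tibble(
    region = region,
    time_h = as.numeric(times),
    ip_over_input = remaining,
    removed_percent = 100 * (1 - remaining / initial)
  )
}

#' Invert the pulldown model for a yield coefficient
#'
#' Given a target pulldown fraction at a known dose and mean per-fragment site
#' count, returns the effective per-site yield `k * w` under the exponential
#' model: `-log(1 - target) / (mean_sites * dose)`. Used to build figure
#' presets from published pulldown fractions.
#'
#' @param target_pulldown Target fraction in (0, 1).
#' @param dose Dose in J/m^2 (> 0).
#' @param mean_sites_per_fragment Mean dipyrimidine sites per fragment (> 0).
#' @return Effective yield coefficient `k*w` per site per (J/m^2).
#' @export
calibrate_yield <- function(target_pulldown, dose, mean_sites_per_fragment) {
  if (target_pulldown <= 0 || target_pulldown >= 1) {
    abort("`target_pulldown` must lie strictly between 0 and 1.")
  }
  if (dose <= 0 || mean_sites_per_fragment <= 0) {
    abort("`dose` and `mean_sites_per_fragment` must be > 0.")
  }
  -log(1 - target_pulldown) / (mean_sites_per_fragment * dose)
}
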