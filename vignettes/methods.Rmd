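---
title: "Models and methods behind telodamage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind telodamage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telodamage)
```

`telodamage` quantifies UV-induced cyclobutane pyrimidine dimer (CPD) damage
and repair in telomeric and control genomic regions. This vignette is the
package's own account of the models it implements, the choices that were
genuinely open, and what its synthetic-data validation does and does not
demonstrate.

## Duplex coordinates and dipyrimidine sites

A duplex is stored as two strands, each written 5′→3′ and indexed 0-based
independently (`duplex_region()`). This strand-local addressing is what makes
strand-restricted simulation and reporting unambiguous: a site on the C-rich
telomeric strand never needs translating through top-strand coordinates.

A dipyrimidine site is any overlapping dinucleotide window whose two bases
are both pyrimidines. Overlapping windows count as distinct sites — CCC holds
two — because each window is an independent photochemical target; this
convention is also the only one that gives the telomeric repeat its
conventional 33.3 sites per 100 nt. The frequency denominator is the total
nucleotide count of *both* strands (2L), for the same reason. IUPAC ambiguity
codes are rejected rather than expanded: every sequence the package handles
is fully specified, and silent expansion would corrupt site counts.

Each TTAGGG/CCCTAA unit carries 4 sites (TT on the G-rich strand; CC, CC, CT
on the C-rich strand) and unit junctions create none, so site counts are
exactly linear in repeat number and split 3:1 between the C-rich and G-rich
strands.

### The oligo catalog, honestly scanned

The built-in catalog of 102-mer dot-blot constructs reproduces the published
designs verbatim: a central 60-mer between two fixed 21-nt flanks X and Y
that contain no dipyrimidine on either strand (verified by
`validate_oligo_design()`). A strict duplex scan of the printed sequences,
however, turns up two caveats that the package reports rather than corrects:

* the non-repeat filler segments used in the series designs carry up to 4
  sites on their *complementary* strand (TC/CT opposite GATG/GATA motifs), so
  the "no dipyrimidine outside the tract" property holds for the flanks but
  only approximately for the fillers;
* the matched-site-count pairing is exact for the 12–48-mer Telo/Equi pairs
  (12, 20, 26, 34 sites) but off by two for the 60-mer pair (40 telomeric vs
  42 non-repeat sites), and the two Equi-diPyr 60-mers carry 42 sites against
  the telomere's 40.

The dot-blot generator consequently uses the *actual* assembled site counts,
and its emitted truth table records a telomere-to-Equi signal ratio slightly
below the nominal 5-fold. Validation reports show the genuine numbers; one
design flag (`counts_equal` for the 60-mer pair) honestly fails.

## The damage model

A UV dose $D$ (J/m²) converts each dipyrimidine site independently into a
CPD with probability

$$p = 1 - \exp(-k\, w_\text{region}\, w_\text{strand}\, D),$$

where $k$ is a per-site yield coefficient (per J/m²) and the $w$ are
dimensionless sensitivity multipliers. Three modelling commitments follow:

* **Independence.** Lesions are independent Bernoulli draws per site.
  Cooperative multi-dimer formation along a destabilized helix is *not*
  modelled — no quantitative cooperative model is available — so all
  sequence-context sensitivity enters through the weights. This is the main
  respect in which the simulator is a calibrated phenomenology rather than a
  mechanistic model.
* **CPD only.** The emulated antibody detects CPD; 6-4 photoproducts are out
  of scope.
* **Calibrated, not predicted, weights.** Region weights are free parameters
  inverted from published pulldown fractions via `calibrate_yield()`
  ($k w = -\ln(1-f)/(m D)$ for target fraction $f$ at mean site count $m$).
  The package makes no attempt to predict the telomere's excess sensitivity
  from sequence; the site-frequency arithmetic shows composition alone cannot
  explain it, which is precisely why the weight is an empirical dial.

Sonication is modelled as i.i.d. uniform fragment lengths on 500–1000 bp with
no sequence bias; for compositionally uniform regions a fragment's site count
is its length times a per-bp density (telomere: 4 sites per 12 bp of repeat,
so a 750 bp fragment carries 250 sites). A fragment is pulled down when it
carries ≥ 1 lesion, giving the closed form $1 - E[\exp(-m k w D)]$ over the
fragment site counts — every Monte Carlo estimate in the package has this
companion expectation, and their agreement within binomial error is a
standing test. The dose–response is linear at low dose with initial slope
$k w \bar m$ and saturates as fragments begin to carry multiple lesions;
`assess_linearity()` locates the resulting slope break.

CPD-per-molecule dose anchors printed for the oligo experiments are mildly
inconsistent between figure legends (0.5 CPD per oligo at 250 J/m² vs 0.1–0.5
over 100–500 J/m²); the presets use the 500 J/m² = 0.5 CPD anchor on a
40-site 102-mer, and `calibrate_yield()` exposes any other anchor.

Excision repair is a single exponential: remaining lesion level
$\propto \exp(-(\rho_\text{region} + \rho_\text{dilution})t)$. The dilution
rate models replication dilution of the signal; with dilution as the only
mechanism all regions decay identically, which is what makes a
repair-incompetent compartment (mitochondrial DNA) a negative control. Rates
in the repair preset are inverted from the published 48-h removal fractions
(70/40/10/10% for p53, 28S, mtDNA, telomere; the telomere value takes the
published "comparable to or less than" the mtDNA control as equal to it).

### Strand presets

The strand-restricted preset calibrates each telomeric strand independently
to its published pulldown fraction (16% C-rich, 6% G-rich at 20 J/m²). The
resulting per-site yields come out nearly equal — the 16:6 split is close to
the 3:1 site-count asymmetry — but the simulator does not force the strand
fractions to compose exactly to the both-strand 14%, because the published
values themselves do not.

## IPoD quantification

Quantitative PCR at a fixed cycle number is proportional to template only on
its log-linear regime, so IP/Input is estimated by comparison to an input
dilution series: `fit_calibration()` fits log(signal) on log(dilution) and
`estimate_ip_over_input()` inverts the line at the IP signal. Numerical
choices:

* **Regime detection** is iterative top-down exclusion with a relative
  residual threshold (default 0.15): while the least-diluted remaining point
  falls short of the line fitted to the others by more than the threshold, it
  is dropped. The rule is deliberately *one-sided*: saturation can only
  depress a signal below the power law, and a symmetric rule turns ordinary
  replicate noise into cascades of spurious exclusions (we observed chains
  reaching calibration failure at 10% noise). Degenerate input — fewer than
  three positive points, or fewer than three surviving points — is an error,
  not a silent fit.
* **Extrapolation** outside the fitted signal range is performed but flagged
  with a warning, never silent.
* **Zero IP signal** maps to exactly 0.
* **Percent removed** interpolates linearly between sampled times; only
  sampled time points are published, and any smoother model would invent
  kinetics between them. Queries outside the observed range are rejected.
* **Breakpoint detection** fits a continuous broken-stick by least squares
  over candidate breakpoints (default: all interior observed doses, a grid
  small enough for exhaustive search; ties broken by the first minimum) and
  reports a break only when the one-segment residual exceeds the two-segment
  residual by a configurable factor (default 4). Perfectly linear and flat
  series short-circuit to "no break".
* **Statistics.** Group comparisons use Welch's unequal-variance two-tailed
  t-test (`stats::t.test`); zero-variance-in-both-groups input is flagged
  degenerate with the continuity values p = 1 (equal means) or 0. No
  multiple-testing correction is applied, matching the analysis the package
  reproduces. Replicates default to triplicate and are combined as means.

Fold sensitivities are reported both uncorrected (ratio of IP/Input
fractions) and corrected for per-site frequency; the correction divides each
fraction by its region's sites per 100 nt.

## Dot-blot series and the phase transition

Grids are normalized per dose to the telomere row (making the analysis
invariant to film exposure), Welch-tested for dose dependence of the ratios,
and pooled by arithmetic mean when none is detected (α = 0.05, two-tailed).
Insufficient replication pools anyway but flags the result.

For repeat-length series, the expected baseline is *linear through the origin
in the dipyrimidine-tract site count* (4 sites per 6-nt repeat), anchored to
1 at the 12-mer. The tract count — not the whole-central-60-mer count — is
the right linear predictor because the filler's few complementary-strand
sites are constant across the series and cancel in the 12-mer normalization
only to first order; using the tract keeps the baseline exactly proportional
to repeat number, which is the stated expectation being tested against.

`detect_phase_transition()` computes the excess ratio
$r(n) = \text{telo}_{norm}(n)/\text{baseline}(n)$ and reports the smallest
repeat count at which $r$ exceeds a threshold (default 1.5) *and stays above
it for every longer construct*. A sustained-threshold rule was chosen over a
formal change-point likelihood because no statistical model of the transition
exists to be fitted — only a plotted break; the default threshold sits midway
between the pre-transition level (1) and the first published excess (3), and
the detector's output is insensitive to it anywhere in roughly (1.2, 2.5)
given those levels. The plateau fold averages the two longest tracts (48 and
60 nt), where the published series flattens. A series that never exceeds the
threshold reports no onset rather than forcing one.

## Mean TRF and shortening

Lane profiles are divided into 75 equal intervals in lane-position space
(matching the published procedure; the discretization error of the statistic
is below 2% against a 300-bin reference on smooth lanes). Fragment length at
a bin center comes from piecewise-linear interpolation of log(length) against
position through the marker ladder — the standard agarose migration
approximation; no migration model is published, so the standard one is
assumed. Background is a per-lane constant, by default the lane's minimum raw
intensity (an estimate of blank film level); the published method does not
describe its background procedure. The statistic

$$\bar L = \frac{\sum_i OD_i}{\sum_i OD_i / L_i}$$

is reported in kb. It is invariant to uniform intensity rescaling, equals the
interval length exactly for a delta lane, and is bounded by the occupied
lengths. TRF fragments include a pre-telomeric portion; the statistic is
computed on TRF lengths as-is and the caveat is documentation, not a
correction.

Shortening is summarized as a per-dose least-squares rate (kb/passage); the
dose effect is tested by comparing final-passage mean TRF of each dose
against dose 0 (Welch), an endpoint comparison because only two passages are
available — a slope comparison would be the same two points.

## The synthetic generators: what they emulate and what they don't

The generators (`generate_gel_signals()`, `generate_dotblot()`,
`generate_trf_lanes()`) produce tables in exactly the shape the
quantification functions consume, under named presets whose parameters are
the published anchor numbers; every parameter carries a provenance note, and
every generator emits its truth alongside the data.

* Noise is multiplicative log-normal, mean 1, because densitometry error is
  scale-proportional. The default relative SD of 10% (5% for the dose-series
  and TRF presets) is a working value: replicate scatter is not published
  numerically, so this knob is a modelling stand-in, not a claim.
* The gel generator holds PCR in its log-linear regime (signal strictly
  proportional to template) with a constant film background; it does not
  model cycle-to-cycle amplification chemistry, primer competition, or the
  telomere smear's shape. The input dilution series spans 1 to 2⁻⁹ so that
  every preset's true IP/Input lies inside the calibrated range.
* The dot-blot generator makes intensity proportional to expected CPD per
  molecule times a sensitivity multiplier; it does not model membrane
  transfer, antibody binding kinetics, or film response curves.
* The TRF generator produces a log-normal length smear (width sdlog = 0.25,
  a working value) with log-linear migration and a 10-rung ladder; its truth
  is the directly summed statistic on the noise-free fine profile, not the
  log-normal's analytic mean, so binning recovery is tested against what the
  lane actually contains. Initial repair-preset IP/Input levels are scaled
  from the 20 J/m² fractions (the unpublished mtDNA level is set equal to
  the other single-copy controls); only removal *ratios* matter to the
  percent-removed statistic.

Passing recovery tests on these fixtures therefore shows that the
quantification chain is unbiased and correctly calibrated *under the model's
own assumptions* — proportional signals, independent lesions, log-normal
noise. It cannot show robustness to the failure modes real membranes and
gels exhibit (spatial background gradients, saturated film, lane distortion),
which are out of scope.

## Problem sizes and determinism

Monte Carlo checks use 10⁵ fragments for simulator-vs-closed-form agreement
(3 binomial standard errors) and 2×10⁴ fragments × 20 seeded replicates for
pipeline recovery; recovery tolerances are ±15% relative for pulldown
fractions, ±5 percentage points for removal percentages, ±15% for pooled
dot-blot ratios, and ±5% for mean TRF — chosen to sit well above the
estimators' standard errors at these sizes while still binding. All
stochastic functions either take an explicit seed or draw from the ambient
RNG stream (`seed = NULL`) so that a single top-level seed governs a whole
pipeline in documented call order; identical seeds give bit-identical
outputs.

## Known limitations

* Lesion independence: no cooperative or multiply-damaged-site modelling, so
  the simulator cannot generate the double-strand-break precursors that
  motivate part of the biology.
* Region sensitivity weights are calibrated, not predicted; the package
  quantifies the telomere's excess sensitivity but does not explain it.
* The genomic p53 and 28S fragment sequences are not published; their site
  frequencies (29.5 and 28.9 per 100 nt) are accepted as constants rather
  than recomputed from sequence.
* One published oligo is internally inconsistent across its two printed
  descriptions (repeat unit TTCAGG in the table vs TTCGGG in a legend); the
  catalog stores the tabulated sequence.
* No image processing: all intensities are assumed already extracted from
  gels, membranes, or films.
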