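# telodamage

Quantitative tools for studying UV-induced cyclobutane pyrimidine dimer (CPD)
damage and repair in telomeric DNA.

Human telomeres are tandem arrays of the hexamer 5′TTAGGG/3′ (C-rich strand
5′CCCTAA), a sequence dense in dipyrimidine sites — the only positions where
UV light can form CPDs. Measuring how much damage telomeres accumulate, how
strand-specific it is, whether it is repaired, and whether chronic damage
accelerates telomere shortening requires a chain of quantitative steps:
counting target sites strand-specifically, converting immunoprecipitation
densitometry into absolute IP/Input fractions through dilution calibration
curves, normalizing dot-blot series against the linear site-count
expectation, and summarizing telomere restriction fragment (TRF) smears into
a mean length. `telodamage` implements that chain as a tidyverse-style R
package, together with a seeded simulator of the underlying damage process so
every stage can be exercised and validated on synthetic data with known
truth. It is aimed at DNA-repair and telomere researchers who want to analyze
such measurements, or to study the statistical behaviour of these assays.

## The quantitative core

* **Target-site analysis.** A dipyrimidine site is an overlapping
  dinucleotide window of two pyrimidines (TT, TC, CT, CC) on one strand;
  overlapping windows count separately. The site frequency of a duplex is
  `100 · n_sites / (2L)` per 100 nucleotides. Each TTAGGG/CCCTAA unit carries
  4 sites (TT on the G-rich strand; CC, CC, CT on the C-rich strand), giving
  the telomere exactly 100/3 ≈ 33.3 sites per 100 nt, with a 3:1 C-rich:G-rich
  strand asymmetry.
* **Damage model.** A dose *D* (J/m²) lesions each site independently with
  probability `p = 1 − exp(−k·w·D)`; a sonication fragment with *m* sites is
  recovered by the anti-CPD pulldown with probability `1 − exp(−m·k·w·D)`.
  `calibrate_yield()` inverts this to build presets from published pulldown
  fractions, and every Monte Carlo routine has a matching closed form.
* **IPoD quantification.** IP/Input is estimated by inverting a log–log
  dilution calibration curve fitted only on the log-linear PCR regime
  (saturated points are excluded top-down); repair time courses are reduced
  to `percent removed = 100·(1 − frac(t)/frac(0))`, and regional comparisons
  to fold sensitivities with optional per-site correction.
* **Dot-blot series.** Repeat-length series are normalized to their 12-mer,
  compared to the expected linear baseline (signal ∝ tract site count), and
  scanned for a sustained super-linear excess — the operational signature of
  the phase transition in UV sensitivity above 4 telomeric repeats.
* **Mean TRF.** Lanes are divided into 75 intervals and summarized as
  `Σ(ODᵢ) / Σ(ODᵢ/Lᵢ)`, an intensity-weighted harmonic-type mean in kb, used
  to fit shortening rates across passages and test for dose effects.

## Worked example

```r
library(telodamage)
library(dplyr)

dipyr_frequency(build_telomere_repeat(10))
#> [1] 33.33333

# synthetic pulldown densitometry (known truth: telomere 14%, p53/28S 2%)
gel <- generate_gel_signals("fig2", seed = 42)
est <- quantify_ipod(gel, dose) |>
  group_by(region) |>
  summarise(ip_over_input = mean(ip_over_input))
est
#> # A tibble: 3 × 2
#>   region   ip_over_input
#>   <chr>            <dbl>
#> 1 p53             0.0206
#> 2 s28             0.0207
#> 3 telomere        0.141

fold_sensitivity(0.141, 0.0206, freq_a = 33.3, freq_b = 29.5)
#> # A tibble: 1 × 2
#>    fold fold_corrected
#>   <dbl>          <dbl>
#> 1  6.84           6.06

# repeat-length dot-blot series: where does super-linearity set in?
analyze_repeat_series(generate_dotblot("fig4", seed = 42))
#> <phase_transition> onset at 5 repeats; plateau fold 4.10 (threshold 1.50)

# TRF shortening across passages, chronic UVB doses 0-200 J/m^2
trf <- generate_trf_lanes("fig6", seed = 42)
shortening_analysis(trf_lane_table(trf$profiles, trf$ladder, trf$meta))
#> <trf_shortening>
#>   loss rates (kb/passage):
#>     dose      0: -0.243
#>     dose     10: -0.243
#>     dose     50: -0.244
#>     dose    100: -0.243
#>     dose    200: -0.243
#>   dose effect at final passage: 0/4 doses significant
```

Reading the output: the recovered IP/Input fractions reproduce the generator
truth (telomere ~7-fold more damage-prone per fragment than p53), and
correcting for the modest dipyrimidine-frequency difference barely moves the
fold — the hypersensitivity is not a site-count artifact. The series analysis
places the onset of excess UV sensitivity at 5 telomeric repeats with a
plateau of ~4–5×, and the TRF lanes shorten at ~0.25 kb/passage regardless of
UV dose.

## Documentation

The methods vignette (`vignettes/methods.Rmd`) describes the damage model and
its assumptions, the calibration and detection rules, what the synthetic
generators do and do not emulate, and known limitations — including two small
discrepancies in the published oligo catalog that the package reports rather
than hides.
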