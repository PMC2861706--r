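Package: telodamage
Title: Quantifying UV-Induced Pyrimidine Dimer Damage and Repair in Telomeric DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of ultraviolet-light-induced
    cyclobutane pyrimidine dimer (CPD) formation and repair in telomeres and
    other genomic regions. Provides strand-specific enumeration of
    dipyrimidine target sites on duplex DNA, a seeded Monte Carlo simulator of
    CPD induction, sonication fragmentation and antibody pulldown with matched
    closed-form expectations, the immunoprecipitation-of-DNA-damage (IPoD)
    quantification pipeline (dilution calibration curves, IP/Input estimation,
    dose-response normalization and linearity assessment, fold-sensitivity,
    percent-repair time courses), dot-blot series analysis with
    phase-transition detection for tandem-repeat oligonucleotides, the
    intensity-weighted mean telomere restriction fragment (TRF) length
    statistic, and seeded synthetic-data generators that emit their own truth
    parameters for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
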