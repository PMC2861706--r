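# Dot-blot oligo constructs and PCR primer sets used throughout the package.
# Flank X and Y (21 nt each) are dipyrimidine-free on both strands so that all
# UV target sites sit in the central 60-mer. Note the listed strand of the
# repeat-bearing constructs is the C-rich strand (unit CCCTAA = complement of
# TTAGGG; the "Repeat" construct unit CCTGAA = complement of TTCAGG).

OLIGO_FLANK5 <- "GTATACGCGTATGCATATGCA"
OLIGO_FLANK3 <- "TGTGCATATGCACACGTGTGC"

oligo_catalog_rows <- function() {
  rep6 <- function(u, n) strrep(u, n)
  tibble::tribble(
    ~name, ~series, ~repeat_unit, ~repeat_count, ~dipyr_region_length, ~central60,
    "Telomere", "fig3", "CCCTAA", 10L, 60L, rep6("CCCTAA", 10),
    "Repeat", "fig3", "CCTGAA", 10L, 60L, rep6("CCTGAA", 10),
    "Equi-diPyr #1", "fig3", NA, 0L, 60L,
    "CCTGACTAGTCGAAATCTCCTCGGACCGAAGAGCTTTGAGGTCCCTGATTGAGCCTGGAA",
    "Equi-diPyr #2", "fig3", NA, 0L, 60L,
    "CCCTTCGTTGGAGTCCCTTTTCCGGGTGGCCTCCAATCCCCATCCTTTGGCTGTTTGGCC",
    "No-diPyr", "fig3", NA, 0L, 0L,
    "CATGTGTGTGCGTATACACGTGCGTACGTATACATATGTGTACGCAGATGCAGCGTGATA",
    "Telo 12", "telo", "CCCTAA", 2L, 12L,
    paste0("CATGTGTGTGCGTATACACGTGCG", rep6("CCCTAA", 2), "TGTGTACGCAGATGCAGCGTGATA"),
    "Equi 12", "equi", NA, 0L, 12L,
    "CATGTGTGTGCGTATACACGTGCGCCCAAAGGCCAGTGTGTACGCAGATGCAGCGTGATA",
    "Telo 24", "telo", "CCCTAA", 4L, 24L,
    paste0("CATGTGTGTGCGTATACA", rep6("CCCTAA", 4), "CGCAGATGCAGCGTGATA"),
    "Equi 24", "equi", NA, 0L, 24L,
    "CATGTGTGTGCGTATACATGCCCCCGGACCAAAGGGCTTTGACGCAGATGCAGCGTGATA",
    "Telo 30", "telo", "CCCTAA", 5L, 30L,
    paste0("CATGTGTGTGCGTATACA", rep6("CCCTAA", 5), "TGCAGCGTGATA"),
    "Telo 36", "telo", "CCCTAA", 6L, 36L,
    paste0("CATGTGTGTGCG", rep6("CCCTAA", 6), "TGCAGCGTGATA"),
    "Equi 36", "equi", NA, 0L, 36L,
    "CATGTGTGTGCGGTAACACCTTGGGCCGAAGGGCTTTGGGGTCCCTAATGCAGCGTGATA",
    "Telo 42", "telo", "CCCTAA", 7L, 42L,
    paste0("CATGTGTGTGCG", rep6("CCCTAA", 7), "GTGATA"),
    "Telo 48", "telo", "CCCTAA", 8L, 48L,
    paste0("CATGTG", rep6("CCCTAA", 8), "GTGATA"),
    "Equi 48", "equi", NA, 0L, 48L,
    "CATGTGTAGCGGAAACCCCCCCGGACCAAAGGGCTTTGAGGTCCCTAATTGGGCGTGATA",
    "Telo 60", "telo", "CCCTAA", 10L, 60L, rep6("CCCTAA", 10),
    "Equi 60", "equi", NA, 0L, 60L,
    "CCCAATTAGCCAAAATCCCCCCGGACCAAGGAACCTTGGGGTCCCTGGTTGGGCCTGGAA"
  )
}

#' Catalog of dot-blot oligonucleotide constructs
#'
#' The built-in 102-mer constructs used in the dot-blot experiments: a central
#' 60-mer (tandem telomeric repeats, a non-telomeric repeat, or a non-repeated
#' "Equi-diPyr" sequence matched in dipyrimidine content) flanked by two fixed
#' dipyrimidine-free 21-mers X and Y. The listed strand of the repeat designs
#' is the C-rich strand; the constructs are duplexes when irradiated.
#'
#' Two catalog caveats, visible in [validate_oligo_design()] reports:
#' the repeat unit of the "Repeat" construct is stored as CCTGAA
#' (complement 5'TTCAGG); and a strict duplex scan finds a few dipyrimidine
#' sites on the complementary strand of the non-repeat filler segments, so the
#' "Equi" matching of site counts is exact for the 12-48-mer pairs but off by
#' two for the 60-mer pair (40 telomeric vs 42 sites).
#'
#' @return A tibble with columns `name`, `series` (`"fig3"`, `"telo"`,
#'   `"equi"`), `repeat_unit` (listed-strand unit or `NA`), `repeat_count`,
#'   `dipyr_region_length` (nt of the dipyrimidine-bearing tract), `central60`,
#'   `flank5`, `flank3`.
#' @export
oligo_catalog <- function() {
  oligo_catalog_rows() |>
    dplyr::mutate(flank5 = OLIGO_FLANK5, flank3 = OLIGO_FLANK3)
}

#' Assemble a catalog oligo into a 102-bp duplex
#'
#' @param name Row label in [oligo_catalog()].
#' @return A [duplex_region()] of length 102 (flank X + central 60-mer +
#'   flank Y, on the listed strand).
#' @export
assemble_oligo <- function(name) {
  cat_ <- oligo_catalog()
  row <- cat_[cat_$name == name, ]
  if (nrow(row) != 1) {
    abort(sprintf("Unknown oligo '%s'; see oligo_catalog()$name.", name))
  }
  duplex_region(paste0(row$flank5, row$central60, row$flank3), name = name)
}

count_sites_touching_span <- function(region, from0, to0) {
  # sites whose window [start, start+1] overlaps [from0, to0) on the
  # coordinate of their own strand; both flanks are 21 nt, so the central
  # span is the same interval on either strand
  sites <- enumerate_dipyr_sites(region)
  sum(sites$start + 1L >= from0 & sites$start <= to0 - 1L)
}

#' Validate a dot-blot oligo design
#'
#' Checks the design rules of the 102-mer constructs: (a) the two 21-nt flanks
#' are dipyrimidine-free on both strands, (b) reports the dipyrimidine site
#' count of the central 60-mer duplex, (c) if a partner construct is supplied,
#' whether the two central counts are equal, and (d) for non-repeat ("Equi")
#' designs, that the central region is not itself arranged as a tandem 6-mer
#' repeat.
#'
#' @param construct Catalog row label of the construct, or a list with
#'   elements `name`, `central60` and optionally `flank5`, `flank3` (defaults:
#'   the catalog flanks X and Y) for an ad-hoc design.
#' @param partner Optional partner construct, same forms as `construct`.
#' @return A one-row tibble: `name`, `length_ok`, `flanks_dipyr_free`,
#'   `central_sites`, `partner`, `partner_sites`, `counts_equal`,
#'   `non_tandem_ok`.
#' @export
validate_oligo_design <- function(construct, partner = NULL) {
  row <- resolve_construct(construct)
  region <- duplex_region(paste0(row$flank5, row$central60, row$flank3), name = row$name)
  len <- nchar(region$top)
  if (len != 102L) abort(sprintf("Assembled construct is %d bp; expected 102.", len))
  flanks_free <-
    nrow(enumerate_dipyr_sites(duplex_region(row$flank5))) == 0L &&
      nrow(enumerate_dipyr_sites(duplex_region(row$flank3))) == 0L
  central <- count_sites_touching_span(region, 21L, len - 21L)
  non_tandem_ok <- TRUE
  if (grepl("^Equi", row$name)) {
    units <- substring(row$central60, seq(1, 55, by = 6), seq(6, 60, by = 6))
    non_tandem_ok <- length(unique(units)) > 1L
  }
  partner_sites <- NA_integer_
  counts_equal <- NA
  if (!is.null(partner)) {
    prow <- resolve_construct(partner)
    p <- duplex_region(paste0(prow$flank5, prow$central60, prow$flank3), name = prow$name)
    partner_sites <- count_sites_touching_span(p, 21L, nchar(p$top) - 21L)
    counts_equal <- partner_sites == central
  }
  partner_name <- if (is.null(partner)) NA_character_ else resolve_construct(partner)$name
  tibble(
    name = row$name,
    length_ok = len == 102L,
    flanks_dipyr_free = flanks_free,
    central_sites = central,
    partner = partner_name,
    partner_sites = partner_sites,
    counts_equal = counts_equal,
    non_tandem_ok = non_tandem_ok
  )
}

resolve_construct <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    cat_ <- oligo_catalog()
    row <- cat_[cat_$name == x, ]
    if (nrow(row) != 1) abort(sprintf("Unknown oligo '%s'; see oligo_catalog()$name.", x))
    return(row)
  }
  if (is.list(x) && !is.null(x$central60)) {
    return(tibble(
      name = x$name %||% "custom",
      central60 = x$central60,
      flank5 = x$flank5 %||% OLIGO_FLANK5,
      flank3 = x$flank3 %||% OLIGO_FLANK3
    ))
  }
  abort("`construct` must be a catalog name or a list with a `central60` element.")
}

#' PCR primer sets for the IPoD target regions
#'
#' Primers for the telomere (mismatch-containing, annealing to telomeric
#' repeats but not to each other, so the product is a smear), the p53 gene,
#' 28S ribosomal DNA and the mitochondrial CYTB gene.
#'
#' @return A tibble with columns `target`, `fwd`, `rev`, `product_bp`
#'   (`NA` for the telomere smear).
#' @export
primer_catalog <- function() {
  tibble::tribble(
    ~target, ~fwd, ~rev, ~product_bp,
    "telomere",
    "GGTTTTTGAGGGTGAGGGTGAGGGTGAGGGTGAGGGT",
    "TCCCGACTATCCCTATCCCTATCCCTATCCCTATCCCTA", NA_integer_,
    "p53", "CTGCCTCTTGCTTCTCTTTTCC", "GGTTTCTTCTTTGGCTGGG", 309L,
    "28S", "GTAGAATAAGTGGGAGGCCCCCGG", "AGGCCCCGCTTTCACGGTCTGTATTCG", 368L,
    "CYTB", "CCCTAGCCAACCCCTTAAAC", "TTGGCTTAGTGGGCGAAATA", 297L
  )
}
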