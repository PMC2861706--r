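#' Reverse complement of a DNA sequence
#'
#' Watson-Crick complement, reversed. Only the unambiguous alphabet A, C, G, T
#' is accepted; IUPAC ambiguity codes are rejected because every sequence this
#' package handles is fully specified.
#'
#' @param seq Character vector of DNA sequences (5'->3').
#' @return Character vector of the same length, each element the reverse
#'   complement of the input (5'->3').
#' @examples
#' reverse_complement("TTAGGG") # "CCCTAA"
#' @export
reverse_complement <- function(seq) {
  check_dna(seq)
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
  unname(out)
}

check_dna <- function(seq, arg = "seq") {
  if (!is.character(seq)) {
    abort(sprintf("`%s` must be a character vector.", arg))
  }
  bad <- grepl("[^ACGT]", seq)
  if (any(bad)) {
    abort(sprintf(
      "`%s` contains characters outside {A,C,G,T}: %s",
      arg, paste(unique(unlist(strsplit(gsub("[ACGT]", "", seq[bad]), ""))), collapse = ", ")
    ))
  }
  invisible(seq)
}

#' Construct a double-stranded DNA region
#'
#' A duplex is stored as two strands, each written 5'->3' and indexed
#' independently (0-based), with the bottom strand the reverse complement of
#' the top. Strand-local addressing is what the strand-restricted damage
#' simulation operates on.
#'
#' @param top Top strand, 5'->3', over A/C/G/T.
#' @param name Region identifier.
#' @param copy_number Copies of this region per genome (positive integer).
#' @return An object of class `duplex_region`: a list with elements `name`,
#'   `top`, `bottom`, `copy_number`.
#' @examples
#' duplex_region("TTAGGG", name = "telomere_unit")
#' @export
duplex_region <- function(top, name = "region", copy_number = 1L) {
  check_dna(top, "top")
  if (length(top) != 1L) abort("`top` must be a single string.")
  if (copy_number < 1) abort("`copy_number` must be a positive integer.")
  structure(
    list(
      name = name,
      top = top,
      bottom = reverse_complement(top),
      copy_number = as.integer(copy_number)
    ),
    class = "duplex_region"
  )
}

#' @export
print.duplex_region <- function(x, ...) {
  cat(sprintf(
    "<duplex_region> %s: %d bp, copy number %d\n", x$name, nchar(x$top), x$copy_number
  ))
  show <- function(s) if (nchar(s) > 60) paste0(substr(s, 1, 57), "...") else s
  cat("  top    5'-", show(x$top), "-3'\n", sep = "")
  cat("  bottom 5'-", show(x$bottom), "-3'\n", sep = "")
  invisible(x)
}

#' Read duplex regions from a FASTA file
#'
#' Each FASTA record becomes a [duplex_region()] with the record sequence as
#' the top strand.
#'
#' @param path Path to an (uncompressed) FASTA file.
#' @return A named list of `duplex_region` objects.
#' @export
read_duplex_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  out <- lapply(seq_along(set), function(i) {
    duplex_region(as.character(set[[i]]), name = names(set)[i])
  })
  setNames(out, names(set))
}

#' Enumerate dipyrimidine sites on both strands of a duplex
#'
#' A dipyrimidine site is an overlapping dinucleotide window whose two bases
#' are both pyrimidines (TT, TC, CT, CC) on one strand; these are the only
#' positions where UV light can form a cyclobutane pyrimidine dimer.
#' Overlapping windows count as distinct sites, so a CCC run holds two sites.
#' Coordinates are 0-based on each strand, each strand read 5'->3'.
#'
#' @param region A [duplex_region()].
#' @return A tibble with columns `strand` ("top"/"bottom"), `start` (0-based
#'   index of the first base of the window on that strand) and `dinucleotide`,
#'   sorted by strand then start. Zero rows if the duplex has no sites.
#' @examples
#' enumerate_dipyr_sites(duplex_region("TTAGGG"))
#' @export
enumerate_dipyr_sites <- function(region) {
  stopifnot(inherits(region, "duplex_region"))
  one_strand <- function(s, label) {
    n <- nchar(s)
    if (n < 2) {
      return(tibble(strand = character(), start = integer(), dinucleotide = character()))
    }
    chars <- strsplit(s, "")[[1]]
    pyr <- chars %in% c("C", "T")
    hit <- which(pyr[-n] & pyr[-1])
    tibble(
      strand = rep(label, length(hit)),
      start = hit - 1L,
      dinucleotide = paste0(chars[hit], chars[hit + 1L])
    )
  }
  dplyr::bind_rows(one_strand(region$top, "top"), one_strand(region$bottom, "bottom")) |>
    dplyr::arrange(match(.data$strand, c("top", "bottom")), .data$start)
}

#' Dipyrimidine site frequency per 100 nucleotides
#'
#' Counts dipyrimidine sites on both strands and divides by the total number
#' of nucleotides on both strands (twice the duplex length). With this
#' convention the human telomeric repeat scores exactly 100/3 = 33.3 sites per
#' 100 nt, the value conventionally quoted for (TTAGGG/CCCTAA)n.
#'
#' @inheritParams enumerate_dipyr_sites
#' @return Sites per 100 nucleotides (scalar).
#' @examples
#' dipyr_frequency(build_telomere_repeat(10)) # 33.33
#' @export
dipyr_frequency <- function(region) {
  stopifnot(inherits(region, "duplex_region"))
  len <- nchar(region$top)
  if (len < 2) abort("Duplex must be at least 2 bp for a dipyrimidine frequency.")
  100 * nrow(enumerate_dipyr_sites(region)) / (2 * len)
}

#' Build a telomeric repeat duplex
#'
#' Concatenates `n` copies of the human telomeric hexamer (top strand
#' 5'TTAGGG, bottom strand 5'CCCTAA). Each unit contributes four dipyrimidine
#' sites: one TT on the G-rich strand and CC, CC, CT on the C-rich strand;
#' unit junctions create no additional sites.
#'
#' @param n Number of repeats (>= 1).
#' @param unit Repeat unit for the top strand; default the human telomere.
#' @return A [duplex_region()] named `"telomere"` (or `"<unit>_repeat"`).
#' @export
build_telomere_repeat <- function(n, unit = "TTAGGG") {
  if (n < 1) abort("`n` must be >= 1.")
  check_dna(unit, "unit")
  name <- if (identical(unit, "TTAGGG")) "telomere" else paste0(unit, "_repeat")
  duplex_region(strrep(unit, n), name = name)
}

#' Minimal mismatch count between a primer and a tandem repeat
#'
#' Slides the primer along an effectively infinite concatenation of the repeat
#' unit and reports the minimum Hamming distance over all phase offsets,
#' separately for the unit as given and for its reverse complement. Used to
#' check telomere PCR primers that carry deliberate mismatches so that they
#' anneal to telomeric DNA but not to each other.
#'
#' @param primer Primer sequence, 5'->3'.
#' @param repeat_unit Repeat unit, 5'->3' (e.g. "TTAGGG").
#' @return A tibble with one row per orientation: columns `orientation`
#'   ("unit"/"revcomp"), `unit` (the reference repeat used) and `mismatches`
#'   (minimum over all registers).
#' @export
count_primer_repeat_mismatches <- function(primer, repeat_unit) {
  check_dna(primer, "primer")
  check_dna(repeat_unit, "repeat_unit")
  if (nchar(primer) < nchar(repeat_unit)) {
    abort("`primer` must be at least as long as `repeat_unit`.")
  }
  min_over_registers <- function(unit) {
    k <- nchar(unit)
    conc <- strrep(unit, ceiling(nchar(primer) / k) + 1L)
    p <- strsplit(primer, "")[[1]]
    cc <- strsplit(conc, "")[[1]]
    min(vapply(seq_len(k), function(off) {
      sum(p != cc[off:(off + length(p) - 1L)])
    }, integer(1)))
  }
  tibble(
    orientation = c("unit", "revcomp"),
    unit = c(repeat_unit, reverse_complement(repeat_unit)),
    mismatches = c(
      min_over_registers(repeat_unit),
      min_over_registers(reverse_complement(repeat_unit))
    )
  )
}
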