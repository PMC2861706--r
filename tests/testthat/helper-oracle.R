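# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the package's own site-scanning code paths.

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# plain-loop reverse complement, independent of Biostrings
oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# plain-loop dipyrimidine window scan of one strand
oracle_strand_sites <- function(s) {
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  if (n < 2) return(integer())
  hits <- integer()
  for (i in seq_len(n - 1)) {
    if (chars[i] %in% c("C", "T") && chars[i + 1] %in% c("C", "T")) {
      hits <- c(hits, i - 1L)
    }
  }
  hits
}

oracle_duplex_site_count <- function(top) {
  length(oracle_strand_sites(top)) + length(oracle_strand_sites(oracle_revcomp(top)))
}
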