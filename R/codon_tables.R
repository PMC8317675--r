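#' The 64 codons in fixed lexicographic order
#'
#' Order is lexicographic over the alphabet A < C < G < T (AAA ... TTT), the
#' order used for every count matrix and usage vector in the package, so that
#' serialized tables are reproducible and column positions are stable.
#'
#' @return Character vector of length 64.
#' @export
#' @examples
#' codon_order()[1:4]
codon_order <- function() {
  nt <- c("A", "C", "G", "T")
  g <- expand.grid(p3 = nt, p2 = nt, p1 = nt, stringsAsFactors = FALSE)
  paste0(g$p1, g$p2, g$p3)
}

#' The 4096 ordered codon pairs in fixed lexicographic order
#'
#' A codon pair is two consecutive in-frame codons, written as the
#' concatenated hexamer (first codon then second). Lexicographic order over
#' hexamers coincides with lexicographic order over (codon1, codon2).
#'
#' @return Character vector of length 4096.
#' @export
codon_pair_order <- function() {
  cds <- codon_order()
  g <- expand.grid(second = cds, first = cds, stringsAsFactors = FALSE)
  paste0(g$first, g$second)
}

#' Synonymous codon families under the standard genetic code
#'
#' Maps each codon to its amino acid; the three stop codons (TAA, TAG, TGA)
#' are treated as a single 3-member synonymous family, labelled `"*"`.
#'
#' @return Named character vector: names are the 64 codons in
#'   [codon_order()], values the one-letter amino acid (or `"*"` for stop).
#' @export
#' @examples
#' table(codon_families())["G"]  # four glycine codons
codon_families <- function() {
  fam <- Biostrings::GENETIC_CODE[codon_order()]
  names(fam) <- codon_order()
  fam
}

# sense codons (non-stop), used by the synthetic generator
sense_codons <- function() {
  fam <- codon_families()
  names(fam)[fam != "*"]
}
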