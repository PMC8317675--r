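#' Read an HTSeq-style two-column count file
#'
#' Expects tab-separated `gene_id<TAB>count` rows with no header; summary
#' rows whose id starts with `"__"` (e.g. `__no_feature`) are dropped.
#'
#' @param path File path.
#' @return Named numeric vector of counts.
#' @export
read_htseq_counts <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("gene_id", "count"))
  df <- df[!startsWith(df$gene_id, "__"), , drop = FALSE]
  stats::setNames(as.numeric(df$count), df$gene_id)
}

#' Convert raw counts to transcripts per million (TPM)
#'
#' `TPM_g = (count_g / L_g) / sum_h(count_h / L_h) * 1e6`, with `L_g` the
#' gene's effective length in nucleotides (here the primary-transcript CDS
#' length). Genes present in the counts but absent from `lengths` are
#' dropped, with the dropped tally recorded in attribute `"n_dropped"`;
#' genes with a length but no count get TPM 0.
#'
#' @param counts Named numeric vector of raw counts.
#' @param lengths Named numeric vector of per-gene lengths (nt), all > 0.
#' @return Named TPM vector over `names(lengths)`, summing to 1e6.
#' @export
counts_to_tpm <- function(counts, lengths) {
  stopifnot(all(lengths > 0))
  dropped <- sum(!(names(counts) %in% names(lengths)))
  counts <- counts[names(counts) %in% names(lengths)]
  full <- stats::setNames(numeric(length(lengths)), names(lengths))
  full[names(counts)] <- counts
  rate <- full / lengths
  total <- sum(rate)
  if (total <= 0) stop("all counts are zero; TPM undefined")
  tpm <- rate / total * 1e6
  attr(tpm, "n_dropped") <- dropped
  tpm
}

# Shared core: expression-weighted column sums of a count matrix,
# renormalized to `scale`. Genes missing on either side are dropped.
.weighted_usage <- function(weights, counts, scale) {
  shared <- intersect(names(weights), rownames(counts))
  if (length(shared) == 0L) stop("no genes shared between expression and counts")
  dropped <- (length(weights) - length(shared)) +
    (nrow(counts) - length(shared))
  w <- weights[shared]
  v <- as.vector(crossprod(counts[shared, , drop = FALSE], w))
  total <- sum(v)
  if (total <= 0) stop("zero total weight; usage undefined")
  out <- stats::setNames(v / total * scale, colnames(counts))
  attr(out, "n_dropped") <- dropped
  out
}

#' Transcriptome-weighted codon usage
#'
#' Weights each gene's codon counts by its expression (TPM) and normalizes
#' the pooled vector to 1,000: the codon composition of the expressed mRNA
#' pool, in codons per thousand. The result is invariant to positive
#' rescaling of the expression vector, so raw TPM, median TPM, or any
#' proportional weights give the same usage.
#'
#' @param tpm Named numeric expression vector (TPM or proportional weights).
#' @param counts Genes x 64 codon count matrix (e.g.
#'   `build_count_matrices()$codon`). Genes missing from either side are
#'   dropped (tally in attribute `"n_dropped"`).
#' @return Named numeric vector over the 64 codons, summing to 1,000.
#' @export
weighted_usage <- function(tpm, counts) {
  .weighted_usage(tpm, counts, 1000)
}

#' Transcriptome-weighted codon-pair usage
#'
#' As [weighted_usage()], over the 4096 ordered codon pairs, normalized to
#' one million (frequency per million codon pairs).
#'
#' @param tpm Named numeric expression vector.
#' @param pairs Genes x 4096 codon-pair count matrix.
#' @return Named numeric vector over the 4096 pairs, summing to 1e6.
#' @export
weighted_pair_usage <- function(tpm, pairs) {
  .weighted_usage(tpm, pairs, 1e6)
}

#' Construct a median pseudo-sample for a tissue group
#'
#' Per-gene median TPM across the group's samples (even n: mean of the two
#' central order statistics). The result is not renormalized; the weighting
#' step normalizes anyway.
#'
#' @param tpm_table Genes x samples numeric matrix.
#' @return Named numeric vector (one value per gene).
#' @export
median_sample <- function(tpm_table) {
  stopifnot(is.matrix(tpm_table), ncol(tpm_table) >= 1L)
  apply(tpm_table, 1L, stats::median)
}

#' Unweighted (genomic) codon or codon-pair usage
#'
#' Pools counts over all genes with no expression weighting and normalizes
#' to the scale: the "genomic" baseline point used alongside the weighted
#' tissues in ordinations.
#'
#' @param counts Genes x 64 (or genes x 4096) count matrix.
#' @param scale 1000 for codons (default), 1e6 for pairs.
#' @return Named numeric vector summing to `scale`.
#' @export
genomic_usage <- function(counts, scale = 1000) {
  stopifnot(nrow(counts) >= 1L)
  v <- colSums(counts)
  v / sum(v) * scale
}

#' Relative synonymous codon usage (RSCU)
#'
#' `RSCU_c = usage_c / mean(usage over c's synonymous family)` under the
#' standard genetic code; 1 means no preference within the family. The three
#' stop codons form one 3-member family. Single-codon families (ATG-Met,
#' TGG-Trp) have RSCU exactly 1 whenever used. Families with zero total
#' usage get `NA` (undefined preference).
#'
#' RSCU is scale-free: per-thousand usage and raw counts give identical
#' values.
#'
#' @param usage Named numeric vector over the 64 codons.
#' @return Named numeric vector of RSCU values (`NA` for zero-usage
#'   families).
#' @export
#' @examples
#' u <- setNames(numeric(64), codon_order())
#' u[c("GGT", "GGC", "GGA", "GGG")] <- c(10, 20, 30, 40)
#' rscu(u)[c("GGT", "GGC", "GGA", "GGG")]
rscu <- function(usage) {
  stopifnot(!is.null(names(usage)), all(codon_order() %in% names(usage)))
  usage <- usage[codon_order()]
  fam <- codon_families()
  out <- stats::setNames(rep(NA_real_, 64L), codon_order())
  for (aa in unique(fam)) {
    members <- names(fam)[fam == aa]
    total <- sum(usage[members])
    if (total > 0) out[members] <- usage[members] * length(members) / total
  }
  out
}
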