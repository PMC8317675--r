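# shared helpers: independent counting oracles and small fixture builders

`%||%` <- function(a, b) if (is.null(a)) b else a

# naive substring-scan codon counter, independent of the Biostrings route
naive_count_codons <- function(seq) {
  n <- nchar(seq) %/% 3L
  cods <- substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  out <- stats::setNames(integer(64L), codon_order())
  tab <- table(cods)
  out[names(tab)] <- as.integer(tab)
  out
}

naive_count_pairs <- function(seq) {
  n <- nchar(seq) %/% 3L
  cods <- substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  out <- stats::setNames(integer(4096L), codon_pair_order())
  if (n >= 2L) {
    prs <- paste0(cods[-n], cods[-1L])
    tab <- table(prs)
    out[names(tab)] <- as.integer(tab)
  }
  out
}

random_cds <- function(n_codons) {
  paste(sample(codon_order(), n_codons, replace = TRUE), collapse = "")
}

# random per-thousand usage vector
random_usage <- function() {
  v <- stats::runif(64L, 0.1, 2)
  stats::setNames(v / sum(v) * 1000, codon_order())
}

# minimal cds_set without file round-trip
make_cds <- function(gene_id, transcript_id, sequence) {
  oncocodon:::cds_set(gene_id, transcript_id, sequence, policy = "strict")
}

# metadata row builder for cohort tests
meta_row <- function(file_id, case_id, sample_type = "Primary Tumor",
                     tissue = "lung", diagnosis = "adenocarcinoma",
                     prior = FALSE) {
  data.frame(file_id = file_id, case_id = case_id, sample_type = sample_type,
             tissue_of_origin = tissue, primary_diagnosis = diagnosis,
             prior_treatment = prior, stringsAsFactors = FALSE)
}
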