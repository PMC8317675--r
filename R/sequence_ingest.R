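#' Read coding sequences from a FASTA file
#'
#' Reads a (plain or gzipped) FASTA of per-transcript coding sequences and
#' returns a validated CDS set. Each record must be a complete in-frame CDS:
#' length a positive multiple of 3, alphabet restricted to A/C/G/T. Records
#' violating either rule are skipped with a tally (`policy = "skip"`, the
#' default) or abort the read (`policy = "strict"`).
#'
#' Headers must carry gene and transcript identifiers; `id_pattern` is a
#' regular expression with two capture groups, the first matching the gene id
#' and the second the transcript id. The default matches headers of the form
#' `geneid|transcriptid`.
#'
#' @param path Path to the FASTA file.
#' @param policy `"skip"` to drop invalid records (counted in the
#'   `"n_rejected"` attribute), `"strict"` to raise an error on the first one.
#' @param id_pattern Regex with capture groups `(gene)(transcript)` applied to
#'   the FASTA header (up to the first whitespace).
#' @return A `data.frame` of class `cds_set` with columns `gene_id`,
#'   `transcript_id`, `sequence`, `length`, and attribute `n_rejected`.
#' @export
read_cds_fasta <- function(path, policy = c("skip", "strict"),
                           id_pattern = "^([^|]+)\\|(.+)$") {
  policy <- match.arg(policy)
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("no records in FASTA file: ", path)
  headers <- sub("\\s.*$", "", names(seqs))
  m <- regmatches(headers, regexec(id_pattern, headers))
  bad_header <- vapply(m, length, 1L) < 3L
  if (any(bad_header)) {
    stop("FASTA headers do not match id_pattern: ",
         paste(utils::head(headers[bad_header], 3), collapse = ", "))
  }
  gene_id <- vapply(m, `[`, "", 2L)
  transcript_id <- vapply(m, `[`, "", 3L)
  sequence <- as.character(seqs)
  cds_set(gene_id, transcript_id, sequence, policy = policy)
}

# Validate sequences and assemble the cds_set data.frame shared by the FASTA
# and GTF ingest paths.
cds_set <- function(gene_id, transcript_id, sequence,
                    policy = c("skip", "strict")) {
  policy <- match.arg(policy)
  len <- nchar(sequence)
  ok_frame <- len > 0L & len %% 3L == 0L
  ok_alpha <- !grepl("[^ACGT]", sequence)
  ok <- ok_frame & ok_alpha
  if (policy == "strict" && any(!ok)) {
    first <- which(!ok)[1L]
    stop("invalid CDS for transcript ", transcript_id[first],
         if (!ok_frame[first]) " (length not a positive multiple of 3)"
         else " (non-ACGT characters)")
  }
  out <- data.frame(gene_id = gene_id[ok],
                    transcript_id = transcript_id[ok],
                    sequence = sequence[ok],
                    length = len[ok],
                    stringsAsFactors = FALSE)
  if (nrow(out) == 0L) stop("no valid CDS records")
  attr(out, "n_rejected") <- sum(!ok)
  class(out) <- c("cds_set", "data.frame")
  out
}

#' Extract coding sequences from a genome FASTA plus GTF annotation
#'
#' Collects `CDS` features per transcript from a Gencode-dialect GTF,
#' concatenates the segments in transcript order (5' to 3'), and
#' reverse-complements minus-strand transcripts. GTF coordinates are treated
#' as 1-based inclusive. Transcripts whose contig is missing from the genome
#' are skipped with a warning; assembled sequences failing the in-frame /
#' alphabet invariants are handled per `policy` as in [read_cds_fasta()].
#'
#' @param genome Path to the genome FASTA, or a named `DNAStringSet`.
#' @param gtf Path to the GTF file (must contain CDS features with
#'   `gene_id` and `transcript_id` attributes).
#' @param policy Invalid-CDS policy, see [read_cds_fasta()].
#' @return A `cds_set` (see [read_cds_fasta()]).
#' @export
extract_cds_from_gtf <- function(genome, gtf, policy = c("skip", "strict")) {
  policy <- match.arg(policy)
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  gr <- rtracklayer::import(gtf, format = "gtf")
  gr <- gr[gr$type == "CDS"]
  if (length(gr) == 0L) stop("no CDS features in GTF: ", gtf)
  missing_contig <- !(as.character(GenomicRanges::seqnames(gr)) %in%
                        names(genome))
  if (any(missing_contig)) {
    warning("skipping CDS on contigs absent from genome: ",
            paste(unique(as.character(
              GenomicRanges::seqnames(gr[missing_contig]))), collapse = ", "))
    gr <- gr[!missing_contig]
    if (length(gr) == 0L) stop("no CDS features on known contigs")
  }
  df <- data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   gene_id = gr$gene_id,
                   transcript_id = gr$transcript_id,
                   stringsAsFactors = FALSE)
  pieces <- split(df, df$transcript_id)
  tx_ids <- names(pieces)
  seqs <- vapply(pieces, function(p) {
    # concatenate in ascending genomic order; for minus-strand transcripts
    # the reverse complement of that concatenation is the 5'->3' CDS
    p <- p[order(p$start), , drop = FALSE]
    segs <- vapply(seq_len(nrow(p)), function(i) {
      as.character(Biostrings::subseq(genome[[p$contig[i]]],
                                      start = p$start[i], end = p$end[i]))
    }, "")
    s <- paste(segs, collapse = "")
    if (p$strand[1L] == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    s
  }, "")
  gene_ids <- vapply(pieces, function(p) p$gene_id[1L], "")
  cds_set(gene_ids, tx_ids, seqs, policy = policy)
}

#' Select one primary transcript per gene
#'
#' The "primary" transcript is, in order of precedence: the transcript
#' carrying a primary/canonical tag when `tags` provides one, else the
#' transcript with the longest CDS, ties broken by lexicographically smallest
#' transcript id.
#'
#' @param cds A `cds_set`.
#' @param tags Optional character vector of transcript ids annotated as
#'   primary/canonical (e.g. from a Gencode `tag "..."` attribute).
#' @return A `cds_set` with exactly one row per gene, ordered by `gene_id`.
#' @export
select_primary_transcript <- function(cds, tags = character()) {
  stopifnot(nrow(cds) >= 1L)
  tagged <- cds$transcript_id %in% tags
  # order so the preferred transcript sorts first within each gene
  o <- order(cds$gene_id, !tagged, -cds$length, cds$transcript_id)
  cds <- cds[o, , drop = FALSE]
  out <- cds[!duplicated(cds$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cds_set", "data.frame")
  out
}

#' Count codons in a coding sequence
#'
#' Counts all in-frame codons, reading frame starting at position 1 and
#' including the stop codon, so the counts sum to `length/3`.
#'
#' @param sequence A CDS as a character string (A/C/G/T, length a multiple
#'   of 3).
#' @return Named integer vector over the 64 codons in [codon_order()].
#' @export
#' @examples
#' count_codons("ATGGAATAA")[c("ATG", "GAA", "TAA")]
count_codons <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            nchar(sequence) %% 3L == 0L, nchar(sequence) > 0L)
  f <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(sequence),
                                            width = 3L, step = 3L)
  f[codon_order()]
}

#' Count overlapping codon pairs in a coding sequence
#'
#' Codon pairs are consecutive in-frame codon bigrams (codon i with codon
#' i+1), counted with overlap: a CDS of n codons yields n - 1 pairs. Pairs
#' never span gene boundaries; a single-codon CDS yields an all-zero vector.
#'
#' @inheritParams count_codons
#' @return Named integer vector over the 4096 pairs in [codon_pair_order()],
#'   named by the concatenated hexamer.
#' @export
count_codon_pairs <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            nchar(sequence) %% 3L == 0L, nchar(sequence) > 0L)
  f <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(sequence),
                                            width = 6L, step = 3L)
  f[codon_pair_order()]
}

#' Build gene-level codon and codon-pair count matrices
#'
#' Rows of both matrices are aligned to a single gene order (sorted
#' `gene_id`); row g of the codon matrix sums to `length(CDS_g)/3` and row g
#' of the pair matrix to that minus one.
#'
#' @param primary A `cds_set` with one row per gene, e.g. from
#'   [select_primary_transcript()].
#' @return A list of class `codon_count_matrices` with elements
#'   `codon` (genes x 64 integer matrix), `pair` (genes x 4096), and
#'   `cds_length` (named vector of CDS lengths in nucleotides).
#' @export
build_count_matrices <- function(primary) {
  if (is.null(primary) || nrow(primary) == 0L) {
    stop("empty CDS mapping; nothing to count")
  }
  if (anyDuplicated(primary$gene_id)) {
    stop("multiple transcripts per gene; call select_primary_transcript first")
  }
  primary <- primary[order(primary$gene_id), , drop = FALSE]
  seqs <- Biostrings::DNAStringSet(primary$sequence)
  codon <- Biostrings::oligonucleotideFrequency(seqs, width = 3L, step = 3L)
  pair <- Biostrings::oligonucleotideFrequency(seqs, width = 6L, step = 3L)
  codon <- codon[, codon_order(), drop = FALSE]
  pair <- pair[, codon_pair_order(), drop = FALSE]
  rownames(codon) <- rownames(pair) <- primary$gene_id
  lens <- stats::setNames(primary$length, primary$gene_id)
  structure(list(codon = codon, pair = pair, cds_length = lens),
            class = "codon_count_matrices")
}

#' Write a count or usage matrix as TSV
#'
#' One row per gene (or sample), first column the row id, then one labelled
#' column per codon or codon pair.
#'
#' @param mat Matrix with row and column names.
#' @param path Output path.
#' @param id_column Name of the first column (default `"gene_id"`).
#' @export
write_matrix_tsv <- function(mat, path, id_column = "gene_id") {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a matrix written by [write_matrix_tsv()]
#'
#' @param path TSV path; first column is taken as row names.
#' @return Numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}
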