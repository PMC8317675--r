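test_that("read_cds_fasta parses records and enforces CDS invariants", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">g1|t1", "ATGGAATAA"), fa)
  cds <- read_cds_fasta(fa)
  expect_equal(nrow(cds), 1L)
  expect_equal(cds$gene_id, "g1")
  expect_equal(cds$transcript_id, "t1")
  expect_equal(cds$length, 9L)
  expect_equal(attr(cds, "n_rejected"), 0L)

  # out-of-frame record: skipped by default, error under strict
  writeLines(c(">g1|t1", "ATGGAATAA", ">g2|t2", "ATGGAATAAC"), fa)
  cds <- read_cds_fasta(fa, policy = "skip")
  expect_equal(nrow(cds), 1L)
  expect_equal(attr(cds, "n_rejected"), 1L)
  expect_error(read_cds_fasta(fa, policy = "strict"), "multiple of 3")

  # ambiguity code: skipped with tally
  writeLines(c(">g1|t1", "ATGGAATAA", ">g2|t2", "ATGNNNTAA"), fa)
  cds <- read_cds_fasta(fa, policy = "skip")
  expect_equal(cds$gene_id, "g1")
  expect_equal(attr(cds, "n_rejected"), 1L)
})

test_that("extract_cds_from_gtf honors coordinates, strand and segment order", {
  dir <- withr::local_tempdir()
  genome_fa <- file.path(dir, "genome.fa")
  gtf <- file.path(dir, "anno.gtf")
  contig <- "AAATTGGCCATAGCA"  # 15 nt
  writeLines(c(">chr1", contig), genome_fa)
  attrs <- function(g, t) {
    sprintf('gene_id "%s"; transcript_id "%s";', g, t)
  }
  writeLines(paste(
    c("chr1", "chr1", "chr1", "chr1"),
    "test", "CDS",
    c(4, 13, 1, 7),           # starts
    c(12, 15, 3, 9),          # ends
    ".", c("+", "+", "-", "-"), "0",
    c(attrs("gA", "tA"), attrs("gB", "tB"),
      attrs("gC", "tC"), attrs("gC", "tC")),
    sep = "\t"), gtf)
  cds <- extract_cds_from_gtf(genome_fa, gtf)
  cds <- cds[order(cds$transcript_id), ]

  # plus strand, positions 4-12, 1-based inclusive
  expect_equal(cds$sequence[cds$transcript_id == "tA"],
               substr(contig, 4, 12))
  # minus strand, genomic segments 1-3 ("AAA") and 7-9 ("GCC"):
  # 5'->3' CDS = revcomp("AAAGCC") = "GGCTTT"
  expect_equal(cds$sequence[cds$transcript_id == "tC"], "GGCTTT")
  expect_equal(nchar(cds$sequence[cds$transcript_id == "tC"]), 3L + 3L)
  # tB has length 3 (13-15)
  expect_equal(cds$sequence[cds$transcript_id == "tB"],
               substr(contig, 13, 15))
})

test_that("CDS counts are invariant under splitting segments at codon boundaries", {
  set.seed(42)
  dir <- withr::local_tempdir()
  genome_fa <- file.path(dir, "g.fa")
  contig <- random_cds(40)  # 120 nt on the contig
  writeLines(c(">c1", contig), genome_fa)
  whole <- paste("c1\tx\tCDS\t1\t120\t.\t+\t0",
                 'gene_id "g"; transcript_id "whole";', sep = "\t")
  split2 <- paste(c("c1\tx\tCDS\t1\t60\t.\t+\t0",
                    "c1\tx\tCDS\t61\t120\t.\t+\t0"),
                  'gene_id "g2"; transcript_id "split";', sep = "\t")
  gtf <- file.path(dir, "a.gtf")
  writeLines(c(whole, split2), gtf)
  cds <- extract_cds_from_gtf(genome_fa, gtf)
  s <- cds$sequence
  names(s) <- cds$transcript_id
  expect_identical(count_codons(s[["whole"]]), count_codons(s[["split"]]))
  expect_identical(s[["whole"]], s[["split"]])
})

test_that("primary transcript selection prefers tag, then longest, then id", {
  cds <- make_cds(c("g1", "g1", "g2", "g2", "g3"),
                  c("t2", "t1", "tb", "ta", "solo"),
                  c(random_cds(100), random_cds(150),
                    random_cds(100), random_cds(100), random_cds(50)))
  sel <- select_primary_transcript(cds)
  expect_equal(sel$transcript_id[sel$gene_id == "g1"], "t1")  # longest wins
  expect_equal(sel$transcript_id[sel$gene_id == "g2"], "ta")  # tie: smallest id
  expect_equal(sel$transcript_id[sel$gene_id == "g3"], "solo")
  # a canonical tag overrides length
  sel2 <- select_primary_transcript(cds, tags = "t2")
  expect_equal(sel2$transcript_id[sel2$gene_id == "g1"], "t2")
})

test_that("codon and pair counting match direct enumeration on small cases", {
  cc <- count_codons("ATGGAATAA")
  expect_equal(sum(cc), 3L)
  expect_equal(unname(cc[c("ATG", "GAA", "TAA")]), c(1L, 1L, 1L))
  expect_equal(unname(count_codons("ATGATGATG")["ATG"]), 3L)

  cp <- count_codon_pairs("ATGGAATAA")
  expect_equal(sum(cp), 2L)
  expect_equal(unname(cp[c("ATGGAA", "GAATAA")]), c(1L, 1L))
  expect_equal(unname(count_codon_pairs("ATGTAA")["ATGTAA"]), 1L)
  expect_equal(sum(count_codon_pairs("ATG")), 0L)

  set.seed(1)
  s999 <- random_cds(333)
  expect_equal(sum(count_codons(s999)), 333L)
})

test_that("counting agrees with the substring-scan oracle on random CDS", {
  set.seed(101)
  for (i in 1:200) {
    s <- random_cds(sample(1:60, 1))
    expect_identical(count_codons(s), naive_count_codons(s))
    expect_identical(count_codon_pairs(s), naive_count_pairs(s))
  }
})

test_that("count matrices share gene order and satisfy row-sum invariants", {
  prim <- make_cds(c("g2", "g1"), c("t2", "t1"), c("ATGGGCTAA", "ATGTAA"))
  mats <- build_count_matrices(prim)
  expect_equal(rownames(mats$codon), c("g1", "g2"))  # sorted gene order
  expect_equal(rownames(mats$pair), rownames(mats$codon))
  expect_equal(unname(rowSums(mats$codon)), c(2, 3))
  expect_equal(unname(rowSums(mats$pair)), c(1, 2))
  expect_equal(unname(mats$cds_length), c(6L, 9L))
  expect_error(build_count_matrices(NULL), "empty")

  # row-sum invariant holds on random gene sets, including 1-codon genes
  set.seed(7)
  lens <- c(1L, sample(2:40, 9))
  prim <- make_cds(sprintf("g%02d", 1:10), sprintf("t%02d", 1:10),
                   vapply(lens, random_cds, ""))
  mats <- build_count_matrices(prim)
  expect_equal(unname(rowSums(mats$codon) * 3), unname(mats$cds_length))
  expect_equal(unname(rowSums(mats$pair)),
               pmax(0, unname(rowSums(mats$codon)) - 1))
})

test_that("count matrices round-trip through TSV serialization", {
  prim <- make_cds(c("g1", "g2"), c("t1", "t2"),
                   c("ATGTAA", "ATGGGCTAA"))
  mats <- build_count_matrices(prim)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(mats$codon, path)
  back <- read_matrix_tsv(path)
  expect_equal(back, mats$codon, ignore_attr = TRUE)
  expect_equal(rownames(back), rownames(mats$codon))
})
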