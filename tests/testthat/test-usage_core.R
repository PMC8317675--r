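test_that("TPM conversion matches the closed form and normalizes to 1e6", {
  tpm <- counts_to_tpm(c(g1 = 100, g2 = 100), c(g1 = 1000, g2 = 2000))
  expect_equal(unname(tpm), c(2e6 / 3, 1e6 / 3), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(sum(tpm), 1e6)

  expect_equal(unname(counts_to_tpm(c(g1 = 5), c(g1 = 300))), 1e6,
               ignore_attr = TRUE)

  # equal counts, equal lengths: uniform
  n <- 8L
  cts <- stats::setNames(rep(7, n), paste0("g", 1:n))
  lens <- stats::setNames(rep(300, n), paste0("g", 1:n))
  expect_equal(unname(counts_to_tpm(cts, lens)), rep(1e6 / n, n),
               ignore_attr = TRUE)

  # genes missing a length are dropped with a tally; absent counts get 0
  tpm <- counts_to_tpm(c(g1 = 10, gX = 99), c(g1 = 300, g2 = 300))
  expect_equal(attr(tpm, "n_dropped"), 1L)
  expect_equal(unname(tpm["g2"]), 0)
  expect_error(counts_to_tpm(c(g1 = 0), c(g1 = 300)), "all counts are zero")
})

test_that("weighted usage obeys symmetry, linearity, identity and scaling", {
  m <- matrix(0, 2, 64, dimnames = list(c("g1", "g2"), codon_order()))
  m["g1", "AAA"] <- 2; m["g2", "GGG"] <- 2
  u <- weighted_usage(c(g1 = 5e5, g2 = 5e5), m)
  expect_equal(unname(u[c("AAA", "GGG")]), c(500, 500))
  u <- weighted_usage(c(g1 = 7.5e5, g2 = 2.5e5), m)
  expect_equal(unname(u[c("AAA", "GGG")]), c(750, 250))
  expect_equal(sum(u), 1000)

  # single expressed gene: that gene's frequencies x 1000
  g <- "ATGGGCTAA"
  mats <- build_count_matrices(make_cds("g1", "t1", g))
  u1 <- weighted_usage(c(g1 = 123), mats$codon)
  expect_equal(unname(u1[c("ATG", "GGC", "TAA")]), rep(1000 / 3, 3))

  # invariance under positive rescaling of the expression vector
  set.seed(3)
  prim <- make_cds(paste0("g", 1:5), paste0("t", 1:5),
                   vapply(rep(30, 5), random_cds, ""))
  mats <- build_count_matrices(prim)
  w <- stats::setNames(stats::runif(5, 1, 100), paste0("g", 1:5))
  expect_equal(weighted_usage(w, mats$codon),
               weighted_usage(w * 17.3, mats$codon), tolerance = 1e-12)
  expect_equal(weighted_pair_usage(w, mats$pair),
               weighted_pair_usage(w * 0.01, mats$pair), tolerance = 1e-12)
  expect_error(weighted_usage(w * 0, mats$codon), "zero total weight")
})

test_that("weighted usage equals the per-codon loop oracle", {
  set.seed(11)
  for (rep in 1:5) {
    n_genes <- sample(1:5, 1)
    prim <- make_cds(paste0("g", 1:n_genes), paste0("t", 1:n_genes),
                     vapply(sample(5:40, n_genes, replace = TRUE),
                            random_cds, ""))
    mats <- build_count_matrices(prim)
    tpm <- stats::setNames(stats::runif(n_genes, 0.1, 10),
                           sort(prim$gene_id))
    # naive loop: accumulate tpm-weighted counts codon by codon
    acc <- stats::setNames(numeric(64), codon_order())
    for (g in names(tpm)) {
      for (cod in codon_order()) {
        acc[cod] <- acc[cod] + tpm[g] * mats$codon[g, cod]
      }
    }
    expect_equal(weighted_usage(tpm, mats$codon),
                 acc / sum(acc) * 1000,
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("pair usage of a single gene and convexity of mixtures", {
  mats <- build_count_matrices(make_cds("g1", "t1", "ATGGAATAA"))
  pu <- weighted_pair_usage(c(g1 = 42), mats$pair)
  expect_equal(unname(pu[c("ATGGAA", "GAATAA")]), c(5e5, 5e5))
  expect_equal(sum(pu), 1e6)

  # weighted usage lies in the convex hull of per-gene usage vectors
  set.seed(5)
  prim <- make_cds(paste0("g", 1:4), paste0("t", 1:4),
                   vapply(rep(25, 4), random_cds, ""))
  mats <- build_count_matrices(prim)
  tpm <- stats::setNames(stats::runif(4), paste0("g", 1:4))
  u <- weighted_usage(tpm, mats$codon)
  per_gene <- t(apply(mats$codon, 1, function(r) r / sum(r) * 1000))
  expect_true(all(u >= apply(per_gene, 2, min) - 1e-9))
  expect_true(all(u <= apply(per_gene, 2, max) + 1e-9))
})

test_that("median sample follows order statistics and commutes with reordering", {
  m <- matrix(c(1, 5, 100), 1, 3, dimnames = list("g1", NULL))
  expect_equal(unname(median_sample(m)), 5)
  m2 <- matrix(c(2, 4), 1, 2, dimnames = list("g1", NULL))
  expect_equal(unname(median_sample(m2)), 3)
  one <- matrix(c(3, 9), 2, 1, dimnames = list(c("g1", "g2"), NULL))
  expect_equal(unname(median_sample(one)), c(3, 9))

  set.seed(9)
  big <- matrix(stats::rlnorm(50), 10, 5,
                dimnames = list(paste0("g", 1:10), NULL))
  expect_equal(median_sample(big), median_sample(big[, c(4, 1, 5, 2, 3)]))
})

test_that("genomic usage pools counts and equals count-proportional weighting", {
  m <- matrix(0, 2, 64, dimnames = list(c("g1", "g2"), codon_order()))
  m["g1", "AAA"] <- 1; m["g2", "AAA"] <- 1; m["g2", "GGG"] <- 2
  gu <- genomic_usage(m)
  expect_equal(unname(gu[c("AAA", "GGG")]), c(500, 500))

  single <- m[1, , drop = FALSE]
  expect_equal(genomic_usage(single), single[1, ] / sum(single[1, ]) * 1000)

  # pooling counts is expression weighting with every gene weighted equally
  set.seed(13)
  for (rep in 1:10) {
    n <- sample(2:6, 1)
    prim <- make_cds(paste0("g", 1:n), paste0("t", 1:n),
                     vapply(sample(4:30, n, replace = TRUE), random_cds, ""))
    mats <- build_count_matrices(prim)
    w <- stats::setNames(rep(1, n), rownames(mats$codon))
    expect_equal(genomic_usage(mats$codon),
                 weighted_usage(w, mats$codon),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("RSCU respects families, singletons and round-trips to usage", {
  u <- stats::setNames(numeric(64), codon_order())
  u[c("GGT", "GGC", "GGA", "GGG")] <- c(10, 20, 30, 40)
  u["ATG"] <- 7
  r <- rscu(u)
  expect_equal(unname(r[c("GGT", "GGC", "GGA", "GGG")]),
               c(0.4, 0.8, 1.2, 1.6))
  expect_equal(unname(r["ATG"]), 1)
  expect_true(all(is.na(r[c("TTT", "TTC")])))  # zero-usage family undefined

  # uniform usage within a 4-codon family gives RSCU 1 everywhere
  u2 <- stats::setNames(numeric(64), codon_order())
  u2[c("GCT", "GCC", "GCA", "GCG")] <- 5
  expect_equal(unname(rscu(u2)[c("GCT", "GCC", "GCA", "GCG")]), rep(1, 4))

  # family sums equal family sizes; usage recovered from RSCU x family mean
  set.seed(21)
  fam <- codon_families()
  for (rep in 1:10) {
    u <- random_usage()
    r <- rscu(u)
    for (aa in unique(fam)) {
      members <- names(fam)[fam == aa]
      expect_equal(sum(r[members]), length(members), tolerance = 1e-9)
      recov <- r[members] * sum(u[members]) / length(members)
      expect_equal(recov, u[members], tolerance = 1e-9)
    }
  }
  # stop codons form one 3-member family
  expect_equal(sum(rscu(random_usage())[c("TAA", "TAG", "TGA")]), 3,
               tolerance = 1e-9)
})

test_that("HTSeq-style count files are read with summary rows dropped", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("g1\t10", "g2\t0", "__no_feature\t100", "__ambiguous\t5"),
             path)
  cts <- read_htseq_counts(path)
  expect_equal(cts, c(g1 = 10, g2 = 0))
})
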