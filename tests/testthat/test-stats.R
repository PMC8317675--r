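test_that("per-case RSCU shifts: zeros, closed form and anti-symmetry", {
  u_norm <- stats::setNames(rep(10, 64), codon_order())
  u_norm[c("GGT", "GGC", "GGA", "GGG")] <- c(10, 20, 30, 40)
  u_tum <- u_norm
  u_tum[c("GGT", "GGC", "GGA", "GGG")] <- c(40, 30, 20, 10)
  usage <- rbind(nf = u_norm, tf = u_tum)
  pairs <- data.frame(case_id = "c1", normal_file = "nf", tumor_file = "tf",
                      stringsAsFactors = FALSE)
  d <- delta_rscu(pairs, usage)
  expect_equal(d$delta[d$codon == "GGT"], 1.6 - 0.4)
  expect_equal(d$delta[d$codon == "GGG"], 0.4 - 1.6)

  # identical vectors give all-zero deltas
  d0 <- delta_rscu(pairs, rbind(nf = u_norm, tf = u_norm))
  expect_true(all(d0$delta == 0))

  # swapping tumor and normal flips every delta
  d_sw <- delta_rscu(data.frame(case_id = "c1", normal_file = "tf",
                                tumor_file = "nf"), usage)
  m <- merge(d, d_sw, by = c("case_id", "codon"))
  expect_equal(m$delta.x, -m$delta.y)
})

test_that("slope Wald test matches the normal-equations oracle", {
  set.seed(71)
  for (rep in 1:10) {
    n <- sample(5:60, 1)
    x <- stats::rnorm(n); y <- 0.5 * x + stats::rnorm(n, sd = 0.3)
    t <- slope_wald_test(x, y)
    # brute-force OLS via normal equations
    beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    alpha_hat <- mean(y) - beta * mean(x)
    resid <- y - alpha_hat - beta * x
    se <- sqrt(sum(resid^2) / (n - 2) / sum((x - mean(x))^2))
    p <- 2 * stats::pt(-abs(beta / se), df = n - 2)
    expect_equal(t$slope, beta, tolerance = 1e-10)
    expect_equal(t$p_value, p, tolerance = 1e-10)
    expect_equal(t$r_squared, stats::cor(x, y)^2, tolerance = 1e-10)
  }
})

test_that("slope Wald test handles exact fits, degeneracy and small n", {
  x <- seq_len(10)
  t <- slope_wald_test(x, -0.7 * x)
  expect_equal(t$slope, -0.7, tolerance = 1e-12)
  expect_equal(t$r_squared, 1)
  expect_lt(t$p_value, 1e-10)
  expect_true(t$significant)
  expect_equal(t$threshold, 0.01 / 3)

  degenerate <- slope_wald_test(rep(1, 5), stats::rnorm(5))
  expect_true(is.na(degenerate$slope))
  expect_false(degenerate$significant)
  expect_error(slope_wald_test(1:2, 1:2), "at least 3")
})

test_that("slope test p-values are calibrated under the null", {
  # identical to the Pearson correlation test for simple OLS, and uniform
  # p-values under independence
  set.seed(73)
  n <- 40
  p_cor <- p_wald <- numeric(400)
  for (i in seq_along(p_wald)) {
    x <- stats::rnorm(n); y <- stats::rnorm(n)
    p_wald[i] <- slope_wald_test(x, y)$p_value
    p_cor[i] <- stats::cor.test(x, y)$p.value
  }
  expect_equal(p_wald, p_cor, tolerance = 1e-10)
  rej <- mean(p_wald < 0.05)
  expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("Wilcoxon screen finds planted shifts with correct directions", {
  set.seed(81)
  n_pairs <- 20L
  base <- matrix(stats::rnorm(n_pairs * 64, 15.6, 1), n_pairs, 64,
                 dimnames = list(NULL, codon_order()))
  shifted <- base
  shifted[, "AAA"] <- shifted[, "AAA"] + 1
  shifted[, "TTT"] <- shifted[, "TTT"] - 1
  res <- codon_wilcoxon_screen(base, shifted)
  expect_equal(res$threshold[1], 0.01 / 64)
  expect_true(res$significant[res$codon == "AAA"])
  expect_true(res$significant[res$codon == "TTT"])
  expect_equal(res$direction[res$codon == "AAA"], "up in tumor")
  expect_equal(res$direction[res$codon == "TTT"], "down in tumor")

  # tumor identical to normal: nothing significant, all-zero diffs flagged
  res0 <- codon_wilcoxon_screen(base, base)
  expect_false(any(res0$significant))
  expect_false(any(res0$defined))

  pairs2 <- data.frame(case_id = c("a", "b"), normal_file = c("n1", "n2"),
                       tumor_file = c("t1", "t2"))
  usage2 <- matrix(1, 4, 64, dimnames = list(c("n1", "n2", "t1", "t2"),
                                             codon_order()))
  expect_error(paired_wilcoxon_screen(pairs2, usage2), "at least 3")
})

test_that("Pratt zero handling agrees with drop-zeros on zero-free data", {
  set.seed(83)
  n_pairs <- 30L
  a <- matrix(stats::rnorm(n_pairs * 64, 15, 1), n_pairs, 64,
              dimnames = list(NULL, codon_order()))
  b <- a + matrix(stats::rnorm(n_pairs * 64, 0, 0.5), n_pairs, 64)
  drop <- codon_wilcoxon_screen(a, b, zeros = "drop")
  pratt <- codon_wilcoxon_screen(a, b, zeros = "pratt")
  # no zeros: both are valid signed-rank tests; p-values track each other
  expect_gt(stats::cor(log(drop$p_value), log(pratt$p_value)), 0.99)
})

test_that("PCA of usage vectors: rank-1 case, determinism, invariances", {
  set.seed(91)
  base <- random_usage()
  dirn <- stats::rnorm(64)
  line <- t(vapply(seq(-2, 2, length.out = 6),
                   function(a) base + a * dirn, numeric(64)))
  rownames(line) <- paste0("s", 1:6)
  p <- pca_usage(line, n_components = 2)
  expect_equal(p$explained_variance[1], 1, tolerance = 1e-9)

  vs <- rbind(line, s7 = random_usage(), s8 = random_usage())
  p1 <- pca_usage(vs)
  p2 <- pca_usage(vs)
  expect_identical(p1$scores, p2$scores)
  expect_true(sum(p1$explained_variance) <= 1 + 1e-12)

  # reordering inputs permutes scores only (sign convention fixed)
  perm <- c(3, 1, 2, 4, 6, 5, 8, 7)
  p3 <- pca_usage(vs[perm, ])
  expect_equal(p3$scores[rownames(vs), ], p1$scores, tolerance = 1e-8)
  expect_error(pca_usage(vs[1:2, ]), "at least 3 vectors")
  expect_error(pca_usage(vs[1:4, ], n_components = 5), "fewer vectors")
})

test_that("hierarchical clustering merges by distance and exports Newick", {
  d <- matrix(c(0, 1, 10,
                1, 0, 10,
                10, 10, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc <- hierarchical_cluster(d)
  expect_equal(sort(hc$hclust$labels[hc$hclust$merge[1, ] * -1]),
               c("A", "B"))  # A,B merge first
  expect_match(hc$newick, "^\\(")
  expect_match(hc$newick, "C")

  # average linkage reproduces an ultrametric exactly (cophenetic check)
  ultra <- matrix(c(0, 2, 8, 8,
                    2, 0, 8, 8,
                    8, 8, 0, 4,
                    8, 8, 4, 0), 4, 4,
                  dimnames = list(letters[1:4], letters[1:4]))
  hc2 <- hierarchical_cluster(ultra, linkage = "average")
  coph <- as.matrix(stats::cophenetic(hc2$hclust))
  expect_equal(coph[letters[1:4], letters[1:4]], ultra)

  # permuting labels permutes leaves only: same cophenetic structure
  perm <- c(3, 1, 4, 2)
  hc3 <- hierarchical_cluster(ultra[perm, perm])
  coph3 <- as.matrix(stats::cophenetic(hc3$hclust))
  expect_equal(coph3[letters[1:4], letters[1:4]], ultra)
})
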