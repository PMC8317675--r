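#' Per-patient RSCU shifts for matched tumor-normal pairs
#'
#' For every paired case and codon, the change in relative synonymous codon
#' usage: `delta = RSCU(tumor) - RSCU(normal)`. Codons whose synonymous
#' family has zero usage in either sample of a pair are undefined for that
#' pair and dropped (tally in attribute `"n_undefined"`).
#'
#' @param pairs Data frame from [find_pairs()] (`case_id`, `normal_file`,
#'   `tumor_file`).
#' @param usage_by_file Files x 64 matrix of per-thousand codon usage
#'   vectors, rownames the file ids.
#' @return Long data frame: `case_id`, `codon`, `delta`.
#' @export
delta_rscu <- function(pairs, usage_by_file) {
  stopifnot(nrow(pairs) >= 1L,
            all(c(pairs$normal_file, pairs$tumor_file) %in%
                  rownames(usage_by_file)))
  out <- vector("list", nrow(pairs))
  n_undef <- 0L
  for (i in seq_len(nrow(pairs))) {
    rn <- rscu(usage_by_file[pairs$normal_file[i], ])
    rt <- rscu(usage_by_file[pairs$tumor_file[i], ])
    d <- rt - rn
    n_undef <- n_undef + sum(is.na(d))
    ok <- !is.na(d)
    out[[i]] <- data.frame(case_id = pairs$case_id[i],
                           codon = names(d)[ok], delta = as.numeric(d[ok]),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "n_undefined") <- n_undef
  res
}

#' OLS regression of one codon's RSCU shift on another, with Wald test
#'
#' Simple least-squares regression of `y` on `x` (typically the per-patient
#' RSCU shifts of two synonymous codons). The null hypothesis of zero slope
#' is tested two-sided with the Wald statistic `slope/SE` against the t
#' distribution on n - 2 degrees of freedom; significance is declared at
#' `alpha / bonferroni_m` (default 0.01/3, for the three synonymous
#' partners tested against a reference codon).
#'
#' @param x,y Paired numeric vectors (same cases, same order), n >= 3.
#' @param bonferroni_m Bonferroni correction factor (default 3).
#' @param alpha Family significance level (default 0.01).
#' @return List of class `slope_test`: `slope`, `intercept`, `r_squared`,
#'   `p_value`, `n`, `threshold` (`alpha/bonferroni_m`), `significant`.
#'   Zero variance in `x` yields `NA` slope with `significant = FALSE`.
#' @export
slope_wald_test <- function(x, y, bonferroni_m = 3L, alpha = 0.01) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations, got ", n)
  threshold <- alpha / bonferroni_m
  if (stats::var(x) == 0) {
    return(structure(list(slope = NA_real_, intercept = NA_real_,
                          r_squared = NA_real_, p_value = NA_real_, n = n,
                          threshold = threshold, significant = FALSE,
                          degenerate = TRUE),
                     class = "slope_test"))
  }
  fit <- stats::lm(y ~ x)
  # summary.lm warns on numerically perfect fits; the p = 0 handling below
  # covers that case
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  p <- if (nrow(co) < 2L) NA_real_ else co["x", "Pr(>|t|)"]
  # exact fits: summary() may report NaN p on zero residual variance
  if (is.nan(p)) p <- 0
  structure(list(slope = unname(stats::coef(fit)["x"]),
                 intercept = unname(stats::coef(fit)["(Intercept)"]),
                 r_squared = sm$r.squared, p_value = p, n = n,
                 threshold = threshold,
                 significant = is.finite(p) && p < threshold,
                 degenerate = FALSE),
            class = "slope_test")
}

#' @export
print.slope_test <- function(x, ...) {
  cat(sprintf(
    "OLS slope test: slope = %.4g, R^2 = %.3f, p = %.3g (n = %d)\n",
    x$slope, x$r_squared, x$p_value, x$n))
  cat(sprintf("  significance threshold %.4g: %s\n", x$threshold,
              if (isTRUE(x$significant)) "significant" else "not significant"))
  invisible(x)
}

# Pratt variant of the signed-rank test: zeros kept in the ranking, normal
# approximation with continuity correction and zero-adjusted variance.
pratt_signed_rank <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  n0 <- sum(d == 0)
  mu <- (n * (n + 1) - n0 * (n0 + 1)) / 4
  ties <- table(r)
  sigma2 <- (n * (n + 1) * (2 * n + 1) - n0 * (n0 + 1) * (2 * n0 + 1)) / 24 -
    sum(ties^3 - ties) / 48
  if (sigma2 <= 0) return(NA_real_)
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
  2 * stats::pnorm(-abs(z))
}

#' Paired Wilcoxon signed-rank screen over all 64 codons
#'
#' For each codon, a two-sided Wilcoxon signed-rank test on the paired
#' per-thousand usage values (tumor vs matched normal across cases), with
#' Bonferroni control over the 64 codons tested: significance at
#' `alpha / bonferroni_m` (default 0.01/64). Direction is the sign of the
#' median paired difference.
#'
#' Zero differences are dropped by default (Wilcoxon's original procedure,
#' as implemented by [stats::wilcox.test()], which uses the exact null
#' distribution for fewer than 50 non-zero pairs without ties); `zeros =
#' "pratt"` keeps them in the ranking with a normal approximation. A codon
#' with all-zero differences has an undefined p-value and is reported as
#' not significant with `defined = FALSE`.
#'
#' @param pairs Data frame from [find_pairs()].
#' @param usage_by_file Files x 64 usage matrix, rownames the file ids.
#' @param bonferroni_m Bonferroni factor (default 64).
#' @param alpha Family significance level (default 0.01).
#' @param zeros `"drop"` (default) or `"pratt"`.
#' @return Data frame: `codon`, `p_value`, `threshold`, `significant`,
#'   `direction` (`"up in tumor"` / `"down in tumor"` / `"none"`),
#'   `defined`.
#' @export
paired_wilcoxon_screen <- function(pairs, usage_by_file, bonferroni_m = 64L,
                                   alpha = 0.01, zeros = c("drop", "pratt")) {
  zeros <- match.arg(zeros)
  if (nrow(pairs) < 3L) stop("need at least 3 pairs, got ", nrow(pairs))
  normal <- usage_by_file[pairs$normal_file, , drop = FALSE]
  tumor <- usage_by_file[pairs$tumor_file, , drop = FALSE]
  codon_wilcoxon_screen(normal, tumor, bonferroni_m = bonferroni_m,
                        alpha = alpha, zeros = zeros)
}

#' Signed-rank screen on aligned normal/tumor usage matrices
#'
#' Matrix-level worker behind [paired_wilcoxon_screen()]; row i of `normal`
#' and `tumor` must belong to the same case.
#'
#' @param normal,tumor Pairs x codons matrices with identical column names.
#' @inheritParams paired_wilcoxon_screen
#' @return As [paired_wilcoxon_screen()].
#' @export
codon_wilcoxon_screen <- function(normal, tumor, bonferroni_m = 64L,
                                  alpha = 0.01, zeros = c("drop", "pratt")) {
  zeros <- match.arg(zeros)
  stopifnot(identical(dim(normal), dim(tumor)), nrow(normal) >= 3L)
  threshold <- alpha / bonferroni_m
  codons <- colnames(normal)
  p_value <- numeric(length(codons))
  med <- numeric(length(codons))
  for (j in seq_along(codons)) {
    d <- tumor[, j] - normal[, j]
    med[j] <- stats::median(d)
    if (zeros == "drop") {
      dnz <- d[d != 0]
      p_value[j] <- if (length(dnz) == 0L) NA_real_ else
        suppressWarnings(
          stats::wilcox.test(dnz, alternative = "two.sided",
                             correct = TRUE)$p.value)
    } else {
      p_value[j] <- pratt_signed_rank(d)
    }
  }
  defined <- !is.na(p_value)
  data.frame(codon = codons, p_value = p_value, threshold = threshold,
             significant = defined & p_value < threshold,
             direction = ifelse(!defined | med == 0, "none",
                                ifelse(med > 0, "up in tumor",
                                       "down in tumor")),
             defined = defined, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Principal component analysis of usage vectors
#'
#' Mean-centered (by default unscaled, since usage values share one scale)
#' PCA of a labelled set of usage vectors. For reproducibility each
#' component's sign is fixed so that its largest-magnitude loading is
#' positive.
#'
#' @param vectors Samples x features matrix, rownames the labels.
#' @param n_components Number of components to return (default 2).
#' @param scale. Divide features by their standard deviation first
#'   (default `FALSE`).
#' @return List: `scores` (samples x n_components), `explained_variance`
#'   (fraction per returned component), `loadings`.
#' @export
pca_usage <- function(vectors, n_components = 2L, scale. = FALSE) {
  stopifnot(is.matrix(vectors))
  if (nrow(vectors) < 3L) stop("need at least 3 vectors for PCA")
  if (n_components > nrow(vectors)) {
    stop("fewer vectors than requested components")
  }
  keep <- if (scale.) apply(vectors, 2L, stats::sd) > 0 else
    rep(TRUE, ncol(vectors))
  pc <- stats::prcomp(vectors[, keep, drop = FALSE], center = TRUE,
                      scale. = scale.)
  k <- min(n_components, ncol(pc$x))
  flip <- vapply(seq_len(k), function(j) {
    l <- pc$rotation[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(pc$x[, seq_len(k), drop = FALSE], 2L, flip, `*`)
  loadings <- sweep(pc$rotation[, seq_len(k), drop = FALSE], 2L, flip, `*`)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = scores, explained_variance = ev[seq_len(k)],
       loadings = loadings)
}

#' Agglomerative clustering of a distance matrix, with Newick export
#'
#' @param d Symmetric distance matrix (or `dist`) with labels.
#' @param linkage One of `"average"` (default), `"complete"`, `"single"`,
#'   `"ward"` (Ward.D2).
#' @return List: `hclust` (the tree), `newick` (serialized string; node
#'   heights are merge distances).
#' @export
hierarchical_cluster <- function(d, linkage = c("average", "complete",
                                                "single", "ward")) {
  linkage <- match.arg(linkage)
  method <- if (linkage == "ward") "ward.D2" else linkage
  hc <- stats::hclust(stats::as.dist(d), method = method)
  list(hclust = hc, newick = ape::write.tree(ape::as.phylo(hc)))
}
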