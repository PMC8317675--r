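#' Mean squared error between two usage or expression vectors
#'
#' `(1/n) * sum((a_i - b_i)^2)`, computed on the vectors' native scales
#' (per-thousand for codon usage, per-million for pair usage, TPM for
#' transcriptomes). The package's scalar measure of tumor-vs-normal
#' divergence.
#'
#' @param a,b Numeric vectors of equal length. If both are named, they are
#'   aligned by name first.
#' @return Nonnegative scalar; 0 iff the vectors are identical.
#' @export
mse <- function(a, b) {
  if (length(a) != length(b)) stop("dimension mismatch: ", length(a),
                                   " vs ", length(b))
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b))) stop("vectors have different names")
    b <- b[names(a)]
  }
  mean((a - b)^2)
}

#' Signed per-codon percent difference between normal and cancer usage
#'
#' For a codon with higher usage in cancer, the difference is reported
#' relative to the normal (smaller) value: `(cancer - normal)/normal * 100`,
#' positive. For a codon higher in normal it is `(normal - cancer)/cancer *
#' 100`, reported with negative sign and direction `"normal"` — i.e. the
#' magnitude is always "X% higher in <the larger side>", relative to the
#' smaller side. A symmetric alternative (difference over the mean of the
#' two) is available via `convention = "mean"`.
#'
#' Codons whose smaller-side value is zero cannot be expressed this way;
#' they are flagged (`defined = FALSE`) and excluded from rankings.
#'
#' @param normal,cancer Named usage vectors on the same scale.
#' @param convention `"smaller"` (default) or `"mean"`.
#' @return Data frame with columns `codon`, `normal`, `cancer`,
#'   `percent_difference` (signed; positive = higher in cancer),
#'   `direction` (`"cancer"`, `"normal"`, or `"equal"`), `defined`.
#' @export
percent_difference <- function(normal, cancer,
                               convention = c("smaller", "mean")) {
  convention <- match.arg(convention)
  stopifnot(!is.null(names(normal)), !is.null(names(cancer)),
            setequal(names(normal), names(cancer)))
  cancer <- cancer[names(normal)]
  lo <- pmin(normal, cancer)
  hi <- pmax(normal, cancer)
  if (convention == "smaller") {
    denom <- lo
  } else {
    denom <- (normal + cancer) / 2
  }
  defined <- denom > 0 | hi == lo   # equal (incl. 0/0) is a defined 0%
  pd <- ifelse(hi == lo, 0, (hi - lo) / denom * 100)
  pd <- ifelse(cancer >= normal, pd, -pd)
  direction <- ifelse(cancer > normal, "cancer",
                      ifelse(normal > cancer, "normal", "equal"))
  data.frame(codon = names(normal), normal = as.numeric(normal),
             cancer = as.numeric(cancer),
             percent_difference = as.numeric(pd),
             direction = direction, defined = defined,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Codons with the greatest usage difference in each direction
#'
#' Ranks the signed percent differences from [percent_difference()] and
#' returns the `k/2` codons most elevated in cancer (`top_up`) and the
#' `k/2` most elevated in normal tissue (`top_down`). Ties are broken
#' lexicographically by codon; undefined codons are excluded.
#'
#' @param normal,cancer Named usage vectors.
#' @param k Even total number of codons to report (default 10).
#' @param convention Passed to [percent_difference()].
#' @return List with data-frame elements `top_up` and `top_down`, each with
#'   `codon` and `percent_difference` (magnitudes).
#' @export
top_differential <- function(normal, cancer, k = 10L,
                             convention = c("smaller", "mean")) {
  stopifnot(k %% 2L == 0L, k >= 2L)
  pd <- percent_difference(normal, cancer, convention)
  pd <- pd[pd$defined, , drop = FALSE]
  half <- k %/% 2L
  up <- pd[order(-pd$percent_difference, pd$codon), , drop = FALSE]
  down <- pd[order(pd$percent_difference, pd$codon), , drop = FALSE]
  list(
    top_up = data.frame(codon = up$codon[seq_len(half)],
                        percent_difference = up$percent_difference[seq_len(half)],
                        stringsAsFactors = FALSE),
    top_down = data.frame(codon = down$codon[seq_len(half)],
                          percent_difference = -down$percent_difference[seq_len(half)],
                          stringsAsFactors = FALSE))
}

#' Pairwise Euclidean distance matrix between usage vectors
#'
#' @param vectors A samples x features numeric matrix (rows are usage
#'   vectors, rownames the labels), or a named list of equal-length vectors.
#' @return Symmetric labelled distance matrix with zero diagonal.
#' @export
euclidean_matrix <- function(vectors) {
  if (is.list(vectors) && !is.data.frame(vectors)) {
    vectors <- do.call(rbind, vectors)
  }
  stopifnot(is.matrix(vectors), nrow(vectors) >= 2L)
  as.matrix(stats::dist(vectors, method = "euclidean"))
}

#' Percentile rank of each codon pair's frequency
#'
#' Rank of each pair among all 4096 frequencies, mean-rank convention for
#' ties, scaled to `[0, 100]` as `(rank - 0.5)/n * 100` so that an all-tied
#' vector scores exactly 50 and a unique maximum scores `100*(n-0.5)/n`.
#'
#' @param pair_usage Numeric vector (typically length 4096).
#' @return Numeric vector of percentiles in `[0, 100]`.
#' @export
pair_percentile_rank <- function(pair_usage) {
  n <- length(pair_usage)
  (rank(pair_usage, ties.method = "average") - 0.5) / n * 100
}

#' Observed/expected ratio for each codon pair
#'
#' Expected pair frequency under independence of consecutive codons, from
#' the marginal codon usage of the same weighted transcriptome:
#' `O/E(c1,c2) = [freq(c1,c2)/1e6] / [freq(c1)/1000 * freq(c2)/1000]`.
#' Pairs whose either marginal codon frequency is zero are undefined (`NA`).
#'
#' @param pair_usage Named per-million pair usage vector
#'   ([weighted_pair_usage()]).
#' @param codon_usage Named per-thousand codon usage vector from the same
#'   transcriptome.
#' @return Named numeric vector of O/E ratios (`NA` where undefined).
#' @export
pair_observed_expected <- function(pair_usage, codon_usage) {
  stopifnot(!is.null(names(pair_usage)), !is.null(names(codon_usage)))
  c1 <- substr(names(pair_usage), 1L, 3L)
  c2 <- substr(names(pair_usage), 4L, 6L)
  p1 <- codon_usage[c1] / 1000
  p2 <- codon_usage[c2] / 1000
  expected <- as.numeric(p1 * p2)
  out <- ifelse(expected > 0, (pair_usage / 1e6) / expected, NA_real_)
  stats::setNames(as.numeric(out), names(pair_usage))
}

#' Full divergence report between a normal and a cancer usage vector
#'
#' Bundles the MSE, the per-codon table and the top-k differential codons.
#'
#' @inheritParams top_differential
#' @return List of class `divergence_report`: `mse`, `per_codon`, `top_up`,
#'   `top_down`.
#' @export
divergence_report <- function(normal, cancer, k = 10L,
                              convention = c("smaller", "mean")) {
  convention <- match.arg(convention)
  top <- top_differential(normal, cancer, k, convention)
  structure(list(mse = mse(normal, cancer),
                 per_codon = percent_difference(normal, cancer, convention),
                 top_up = top$top_up, top_down = top$top_down),
            class = "divergence_report")
}

#' @export
print.divergence_report <- function(x, ...) {
  cat("Codon usage divergence report\n")
  cat(sprintf("  MSE (per-thousand scale): %.4g\n", x$mse))
  cat("  Top codons higher in cancer:",
      paste(sprintf("%s (+%.1f%%)", x$top_up$codon,
                    x$top_up$percent_difference), collapse = ", "), "\n")
  cat("  Top codons higher in normal:",
      paste(sprintf("%s (+%.1f%%)", x$top_down$codon,
                    x$top_down$percent_difference), collapse = ", "), "\n")
  invisible(x)
}
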