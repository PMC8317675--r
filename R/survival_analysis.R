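#' Split survival records into top and bottom divergence quartiles
#'
#' Orders cases by the chosen divergence metric and returns the top
#' `ceiling(n/4)` (highest divergence) and bottom `ceiling(n/4)` (lowest)
#' records. Ties at a quartile boundary are resolved deterministically by
#' `case_id` order; an all-tied metric triggers a warning.
#'
#' @param records Data frame with columns `case_id`, `time`, `event`, and
#'   the metric columns (e.g. `mse_codon`, `mse_pair`, `mse_tpm`).
#' @param metric Name of the metric column (default `"mse_codon"`).
#' @return List with data-frame elements `top` and `bottom`.
#' @export
quartile_split <- function(records, metric = "mse_codon") {
  stopifnot(metric %in% names(records))
  if (anyDuplicated(records$case_id)) stop("case_id values are not unique")
  n <- nrow(records)
  if (n < 8L) stop("need at least 8 records for a quartile comparison, got ", n)
  q <- ceiling(n / 4)
  if (length(unique(records[[metric]])) == 1L) {
    warning("all '", metric, "' values equal; quartiles split by case_id order")
  }
  o <- order(records[[metric]], records$case_id)
  records <- records[o, , drop = FALSE]
  list(top = records[seq.int(n - q + 1L, n), , drop = FALSE],
       bottom = records[seq_len(q), , drop = FALSE])
}

#' Kaplan-Meier survival curve with Greenwood confidence bands
#'
#' Product-limit estimate of the survival function, 95% confidence interval
#' from Greenwood's variance with the log-log transform (`conf_type =
#' "plain"` for linear Greenwood), truncated at `horizon` years. The median
#' survival time is the earliest event time at which the estimate drops to
#' 0.5 or below, `NA` ("not reached") otherwise.
#'
#' @param records Data frame with `time` (years, > 0) and `event`
#'   (logical/0-1; TRUE = death observed).
#' @param horizon Truncation horizon in years (default 10).
#' @param conf_type `"log-log"` (default) or `"plain"`.
#' @return List of class `km_curve`: `time`, `surv`, `lower`, `upper`,
#'   `n_risk`, `n_event`, `median` (years or `NA`), `median_reached`,
#'   `n`, `horizon`.
#' @export
km_estimate <- function(records, horizon = 10, conf_type = c("log-log",
                                                             "plain")) {
  conf_type <- match.arg(conf_type)
  stopifnot(nrow(records) >= 1L, all(records$time > 0),
            all(is.finite(records$time)))
  fit <- survival::survfit(
    survival::Surv(records$time, as.integer(records$event)) ~ 1,
    conf.type = if (conf_type == "log-log") "log-log" else "plain",
    conf.int = 0.95)
  keep <- fit$time <= horizon
  med_idx <- which(fit$surv <= 0.5 & fit$n.event > 0)
  med <- if (length(med_idx)) fit$time[min(med_idx)] else NA_real_
  structure(list(time = fit$time[keep], surv = fit$surv[keep],
                 lower = fit$lower[keep], upper = fit$upper[keep],
                 n_risk = fit$n.risk[keep], n_event = fit$n.event[keep],
                 median = if (!is.na(med) && med <= horizon) med else NA_real_,
                 median_reached = !is.na(med) && med <= horizon,
                 n = nrow(records), horizon = horizon),
            class = "km_curve")
}

# step-function lookup of a km_curve component at time t (right-continuous)
.km_at <- function(curve, t, what = "surv") {
  idx <- sum(curve$time <= t)
  if (idx == 0L) {
    return(switch(what, surv = 1, lower = 1, upper = 1))
  }
  val <- curve[[what]][idx]
  # survfit reports NA limits where the variance is zero or the estimate
  # has hit 0; collapse the interval onto the point estimate there
  if (is.na(val)) val <- curve$surv[idx]
  val
}

#' Compare top and bottom divergence-quartile survival curves
#'
#' Reports both medians and, for each whole year of the shared horizon,
#' whether the two groups' 95% confidence intervals overlap. No formal test
#' is computed by default (the comparison is CI separation); set `logrank =
#' TRUE` to add a log-rank p-value, which requires passing the underlying
#' records.
#'
#' @param top,bottom `km_curve` objects on the same horizon.
#' @param top_records,bottom_records Optional record data frames (needed
#'   only for `logrank = TRUE`).
#' @param logrank Add a log-rank test (default `FALSE`).
#' @return List of class `km_comparison`: `median_top`, `median_bottom`,
#'   `overlap_by_year` (data frame `year`, `overlap`), and optionally
#'   `logrank_p`.
#' @export
compare_groups <- function(top, bottom, top_records = NULL,
                           bottom_records = NULL, logrank = FALSE) {
  stopifnot(inherits(top, "km_curve"), inherits(bottom, "km_curve"),
            top$horizon == bottom$horizon)
  years <- seq_len(floor(top$horizon))
  overlap <- vapply(years, function(y) {
    lo_t <- .km_at(top, y, "lower"); hi_t <- .km_at(top, y, "upper")
    lo_b <- .km_at(bottom, y, "lower"); hi_b <- .km_at(bottom, y, "upper")
    lo_t <= hi_b && lo_b <= hi_t
  }, logical(1))
  out <- list(median_top = top$median, median_bottom = bottom$median,
              overlap_by_year = data.frame(year = years, overlap = overlap))
  if (logrank) {
    stopifnot(!is.null(top_records), !is.null(bottom_records))
    df <- rbind(cbind(top_records, .grp = "top"),
                cbind(bottom_records, .grp = "bottom"))
    sd <- survival::survdiff(
      survival::Surv(df$time, as.integer(df$event)) ~ df$.grp)
    out$logrank_p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  }
  class(out) <- "km_comparison"
  out
}

#' @export
print.km_comparison <- function(x, ...) {
  fmt <- function(m) if (is.na(m)) "not reached" else sprintf("%.2f years", m)
  cat("Kaplan-Meier quartile comparison\n")
  cat("  median survival, top (high-divergence) quartile:   ",
      fmt(x$median_top), "\n")
  cat("  median survival, bottom (low-divergence) quartile: ",
      fmt(x$median_bottom), "\n")
  sep <- x$overlap_by_year$year[!x$overlap_by_year$overlap]
  cat("  years with non-overlapping 95% CIs:",
      if (length(sep)) paste(sep, collapse = ", ") else "none", "\n")
  if (!is.null(x$logrank_p)) {
    cat(sprintf("  log-rank p = %.3g\n", x$logrank_p))
  }
  invisible(x)
}
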