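#' Specification for a synthetic tumor-normal cohort
#'
#' Describes a desk-scale cohort with the statistical structure the analysis
#' assumes: a gene set in two classes (background and a "shifted" class
#' enriched/depleted for the target codons), per-case matched normal and
#' tumor expression profiles where the tumor up-regulates the shifted class,
#' GDC-like metadata including distractor records that violate each cohort
#' filter, and survival times whose hazard is coupled to the per-case codon
#' usage divergence.
#'
#' The planted signal is carried by expression fold-changes, not sequence
#' edits, matching the mechanism the pipeline measures (usage shifts arise
#' from expression re-weighting of fixed coding sequences). The class-level
#' fold-change is calibrated at generation time so that the expected
#' transcriptome-weighted usage shift of the first shift target equals its
#' nominal magnitude; per-case heterogeneity then spreads the realized
#' shifts around that value.
#'
#' @param n_genes Number of genes (default 120).
#' @param cds_length_range Range of CDS lengths in codons, start and stop
#'   included (default 100-300).
#' @param shifted_fraction Fraction of genes in the shifted class
#'   (default 0.25).
#' @param shift_targets List of `list(codon=, direction=, magnitude=)`
#'   entries; direction `"up"` or `"down"`, magnitude a relative usage
#'   change (0.2 = 20%). The first entry is calibrated exactly in
#'   expectation; the rest shape the shifted class's codon weights.
#' @param class_weight Codon-weight multiplier applied (or inverted) to the
#'   target codons inside the shifted class (default 8).
#' @param n_cases Number of paired cases (default 100).
#' @param expression_meanlog,expression_sdlog Log-normal baseline expression
#'   parameters (defaults 1 and 1).
#' @param noise_sd Per-gene, per-sample multiplicative log-noise SD as a
#'   fraction (default 0.05). Setting 0 disables both this noise and the
#'   Poisson count sampling, making samples exact expected counts.
#' @param case_spread Log-SD of the per-case fold-change multiplier
#'   (default 0.5): inter-patient heterogeneity of the planted shift.
#' @param library_size Expected total reads per sample (default 5e5);
#'   counts are Poisson draws around expected abundances.
#' @param baseline_hazard Baseline death hazard per year (default 0.15).
#' @param hazard_coupling Log-hazard increase per unit codon-usage MSE
#'   (default 0.125, which under the default planted-shift conditions puts
#'   the top-vs-bottom divergence-quartile hazard ratio near 3).
#' @param censoring_rate Fraction of cases censored, via an independent
#'   exponential censoring process (default 0.25).
#' @param tissue,diagnosis Labels for the cohort's tissue of origin and
#'   diagnosis.
#' @param seed Integer seed; identical spec + seed reproduce every output
#'   byte-for-byte.
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 120L,
                           cds_length_range = c(100L, 300L),
                           shifted_fraction = 0.25,
                           shift_targets = list(
                             list(codon = "GGT", direction = "up",
                                  magnitude = 0.2),
                             list(codon = "GGG", direction = "down",
                                  magnitude = 0.1)),
                           class_weight = 8,
                           n_cases = 100L,
                           expression_meanlog = 1,
                           expression_sdlog = 1,
                           noise_sd = 0.05,
                           case_spread = 0.5,
                           library_size = 5e5,
                           baseline_hazard = 0.15,
                           hazard_coupling = 0.125,
                           censoring_rate = 0.25,
                           tissue = "breast",
                           diagnosis = "ductal carcinoma",
                           seed = 1L) {
  stopifnot(n_genes >= 4L, length(cds_length_range) == 2L,
            all(cds_length_range >= 3L),
            cds_length_range[1L] <= cds_length_range[2L],
            shifted_fraction > 0, shifted_fraction < 1,
            class_weight > 0, n_cases >= 1L, noise_sd >= 0,
            case_spread >= 0, library_size > 0, baseline_hazard > 0,
            censoring_rate >= 0, censoring_rate <= 1,
            length(shift_targets) >= 1L)
  for (t in shift_targets) {
    stopifnot(t$codon %in% sense_codons(),
              t$direction %in% c("up", "down"),
              t$magnitude >= 0, t$magnitude < 1)
  }
  structure(list(n_genes = as.integer(n_genes),
                 cds_length_range = as.integer(cds_length_range),
                 shifted_fraction = shifted_fraction,
                 shift_targets = shift_targets,
                 class_weight = class_weight,
                 n_cases = as.integer(n_cases),
                 expression_meanlog = expression_meanlog,
                 expression_sdlog = expression_sdlog,
                 noise_sd = noise_sd, case_spread = case_spread,
                 library_size = library_size,
                 baseline_hazard = baseline_hazard,
                 hazard_coupling = hazard_coupling,
                 censoring_rate = censoring_rate,
                 tissue = tissue, diagnosis = diagnosis,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# per-class codon sampling weights over the 61 sense codons
.class_weights <- function(spec) {
  sense <- sense_codons()
  bg <- stats::setNames(rep(1, length(sense)), sense)
  shifted <- bg
  for (t in spec$shift_targets) {
    shifted[t$codon] <- if (t$direction == "up") {
      shifted[t$codon] * spec$class_weight
    } else {
      shifted[t$codon] / spec$class_weight
    }
  }
  list(background = bg, shifted = shifted)
}

#' Generate the synthetic gene set
#'
#' Draws each gene's CDS codon by codon from its class's weights: start
#' codon ATG, interior sense codons (no internal stops), one in-frame stop
#' at the end. Gene lengths are uniform over `cds_length_range` (in codons,
#' start and stop included). Deterministic under the spec seed.
#'
#' @param spec A [synthetic_spec()].
#' @param path Optional FASTA output path (headers `gene|transcript`).
#' @return A `cds_set` with an extra `class` column (`"shifted"` /
#'   `"background"`).
#' @export
generate_genes <- function(spec, path = NULL) {
  set.seed(spec$seed)
  w <- .class_weights(spec)
  n_shift <- max(1L, round(spec$n_genes * spec$shifted_fraction))
  classes <- c(rep("shifted", n_shift),
               rep("background", spec$n_genes - n_shift))
  stops <- c("TAA", "TAG", "TGA")
  len_values <- seq.int(spec$cds_length_range[1L], spec$cds_length_range[2L])
  lens <- len_values[sample.int(length(len_values), spec$n_genes,
                                replace = TRUE)]
  seqs <- vapply(seq_len(spec$n_genes), function(i) {
    ww <- w[[classes[i]]]
    interior <- sample(names(ww), lens[i] - 2L, replace = TRUE,
                       prob = ww / sum(ww))
    paste0("ATG", paste(interior, collapse = ""), sample(stops, 1L))
  }, "")
  ids <- sprintf("g%04d", seq_len(spec$n_genes))
  out <- cds_set(ids, sub("^g", "t", ids), seqs, policy = "strict")
  out$class <- classes
  class(out) <- c("cds_set", "data.frame")
  if (!is.null(path)) {
    writeLines(paste0(">", out$gene_id, "|", out$transcript_id, "\n",
                      out$sequence), path)
  }
  out
}

# Solve for the shifted-class expression multiplier m such that the
# expected weighted usage of the first shift target changes by its nominal
# magnitude. Expression weights are proportional to baseline expression.
.calibrate_multiplier <- function(spec, genes, baseline, counts) {
  target <- spec$shift_targets[[1L]]
  shifted <- genes$class == "shifted"
  tot <- rowSums(counts$codon)
  tc <- counts$codon[, target$codon]
  usage_at <- function(m) {
    w <- baseline * ifelse(shifted, m, 1)
    sum(w * tc) / sum(w * tot)
  }
  if (target$magnitude == 0) return(1)
  goal <- usage_at(1) * if (target$direction == "up") {
    1 + target$magnitude
  } else {
    1 - target$magnitude
  }
  limit <- if (target$direction == "up") usage_at(1e9) else usage_at(1e-9)
  feasible <- if (target$direction == "up") goal < limit else goal > limit
  if (!feasible) {
    stop("infeasible shift magnitude ", target$magnitude, " for codon ",
         target$codon, ": class composition cannot reach it")
  }
  f <- function(logm) usage_at(exp(logm)) - goal
  exp(stats::uniroot(f, interval = log(c(1e-9, 1e9)), tol = 1e-12)$root)
}

#' Generate the synthetic cohort: count files, metadata, truth record
#'
#' Per case, one solid-tissue-normal and one primary-tumor sample. Normal
#' expression is the shared log-normal baseline with per-gene multiplicative
#' noise; tumor expression additionally multiplies the shifted gene class by
#' a per-case fold-change (the calibrated class multiplier times a log-normal
#' case factor with SD `case_spread`). Integer counts are Poisson draws of
#' expected read abundances (expression times CDS length, scaled to
#' `library_size`), so the TPM-conversion path is exercised. The metadata
#' includes distractor records violating each cohort filter: one metastatic
#' sample, one prior-treated case (both samples), and an under-threshold
#' cancer type with two tumor samples.
#'
#' The truth record stores the calibrated multiplier, the per-case planted
#' fold-changes, and the realized per-case codon usage MSE (computed from
#' the emitted count files through the package's own TPM and weighting
#' steps), which drives [generate_survival()].
#'
#' @param spec A [synthetic_spec()].
#' @param genes Output of [generate_genes()].
#' @param dir Output directory; count files go to `dir/counts/`, metadata to
#'   `dir/metadata.tsv`, truth to `dir/truth.json`.
#' @return Invisible list: `counts_dir`, `metadata` (data frame),
#'   `metadata_path`, `truth` (list), `truth_path`.
#' @export
generate_cohort <- function(spec, genes, dir) {
  set.seed(spec$seed + 1L)
  counts_dir <- file.path(dir, "counts")
  dir.create(counts_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- build_count_matrices(genes)
  genes <- genes[order(genes$gene_id), , drop = FALSE]  # match matrix order
  baseline <- stats::rlnorm(spec$n_genes, spec$expression_meanlog,
                            spec$expression_sdlog)
  m <- .calibrate_multiplier(spec, genes, baseline, counts)
  # per-case multiplier: calibrated value times log-normal heterogeneity,
  # so the median case carries exactly the planted shift
  case_factor <- exp(stats::rnorm(spec$n_cases, 0, spec$case_spread))
  m_case <- m * case_factor
  shifted <- genes$class == "shifted"
  lens <- counts$cds_length

  emit_counts <- function(file_id, expr) {
    lambda <- spec$library_size * (expr * lens) / sum(expr * lens)
    # noise_sd = 0 is the fully deterministic switch: expected counts are
    # emitted directly, so a zero-shift zero-noise cohort has tumor counts
    # exactly equal to normal counts
    cnt <- if (spec$noise_sd > 0) stats::rpois(length(lambda), lambda) else
      round(lambda)
    df <- data.frame(gene_id = c(genes$gene_id, "__no_feature",
                                 "__ambiguous"),
                     count = c(cnt, 17L, 3L))
    utils::write.table(df, file.path(counts_dir, paste0(file_id, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    stats::setNames(cnt, genes$gene_id)
  }

  meta <- list(); truth_cases <- list()
  for (i in seq_len(spec$n_cases)) {
    case_id <- sprintf("C%04d", i)
    nf <- sprintf("F%04dN", i); tf <- sprintf("F%04dT", i)
    noise <- function() exp(stats::rnorm(spec$n_genes, 0, spec$noise_sd))
    e_norm <- baseline * noise()
    e_tum <- baseline * ifelse(shifted, m_case[i], 1) * noise()
    cn <- emit_counts(nf, e_norm)
    ct <- emit_counts(tf, e_tum)
    u_n <- weighted_usage(counts_to_tpm(cn, lens), counts$codon)
    u_t <- weighted_usage(counts_to_tpm(ct, lens), counts$codon)
    truth_cases[[i]] <- list(case_id = case_id,
                             fold_change = m_case[i],
                             mse_codon = mse(u_n, u_t))
    meta[[length(meta) + 1L]] <- data.frame(
      file_id = c(nf, tf), case_id = case_id,
      sample_type = c("Solid Tissue Normal", "Primary Tumor"),
      tissue_of_origin = spec$tissue, primary_diagnosis = spec$diagnosis,
      prior_treatment = FALSE, stringsAsFactors = FALSE)
  }

  # distractors: one per cohort filter
  emit_counts("FX01M", baseline)
  meta[[length(meta) + 1L]] <- data.frame(
    file_id = "FX01M", case_id = "CX001", sample_type = "Metastatic",
    tissue_of_origin = spec$tissue, primary_diagnosis = spec$diagnosis,
    prior_treatment = FALSE, stringsAsFactors = FALSE)
  for (fid in c("FX02N", "FX02T")) emit_counts(fid, baseline)
  meta[[length(meta) + 1L]] <- data.frame(
    file_id = c("FX02N", "FX02T"), case_id = "CX002",
    sample_type = c("Solid Tissue Normal", "Primary Tumor"),
    tissue_of_origin = spec$tissue, primary_diagnosis = spec$diagnosis,
    prior_treatment = TRUE, stringsAsFactors = FALSE)
  for (fid in c("FX03T", "FX04T")) emit_counts(fid, baseline)
  meta[[length(meta) + 1L]] <- data.frame(
    file_id = c("FX03T", "FX04T"), case_id = c("CX003", "CX004"),
    sample_type = "Primary Tumor", tissue_of_origin = spec$tissue,
    primary_diagnosis = "rare carcinoma", prior_treatment = FALSE,
    stringsAsFactors = FALSE)

  metadata <- do.call(rbind, meta)
  metadata_path <- file.path(dir, "metadata.tsv")
  utils::write.table(metadata, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- list(
    class_multiplier = m,
    shift_targets = spec$shift_targets,
    planted_exclusions = list(sample_type = 1L, prior_treatment = 2L,
                              under_threshold = 2L),
    cases = truth_cases)
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(counts_dir = counts_dir, metadata = metadata,
                 metadata_path = metadata_path, truth = truth,
                 truth_path = truth_path))
}

#' Generate survival times coupled to the planted divergence
#'
#' Each case's death time is exponential with hazard
#' `baseline_hazard * exp(hazard_coupling * mse_codon)`; censoring is an
#' independent exponential process whose rate is set so that the expected
#' censoring fraction equals `censoring_rate` for every case. Deterministic
#' under the spec seed.
#'
#' @param spec A [synthetic_spec()].
#' @param truth Truth record from [generate_cohort()].
#' @param path Optional clinical TSV output (`case_id`, `time_years`,
#'   `event`).
#' @return Data frame: `case_id`, `time` (years), `event` (logical).
#' @export
generate_survival <- function(spec, truth, path = NULL) {
  set.seed(spec$seed + 2L)
  case_id <- vapply(truth$cases, `[[`, "", "case_id")
  mse_codon <- vapply(truth$cases, `[[`, numeric(1), "mse_codon")
  rate <- spec$baseline_hazard * exp(spec$hazard_coupling * mse_codon)
  t_death <- stats::rexp(length(rate), rate)
  if (spec$censoring_rate >= 1) {
    time <- stats::rexp(length(rate), rate)
    event <- rep(FALSE, length(rate))
  } else if (spec$censoring_rate <= 0) {
    time <- t_death
    event <- rep(TRUE, length(rate))
  } else {
    c_rate <- spec$censoring_rate / (1 - spec$censoring_rate) * rate
    t_cens <- stats::rexp(length(rate), c_rate)
    event <- t_death <= t_cens
    time <- pmin(t_death, t_cens)
  }
  out <- data.frame(case_id = case_id, time = time, event = event,
                    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    df <- data.frame(case_id = out$case_id, time_years = out$time,
                     event = as.integer(out$event))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  out
}
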