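#' Build a pipeline run configuration
#'
#' Collects the paths and analysis options for an end-to-end run. All
#' randomness in a run flows from the single `seed`.
#'
#' @param sequences CDS FASTA path (alternative: `genome` + `gtf`).
#' @param counts_dir Directory of per-sample HTSeq-style count files, named
#'   `<file_id>.tsv`.
#' @param metadata Sample metadata TSV (columns of [filter_samples()]).
#' @param clinical Clinical TSV (`case_id`, `time_years`, `event`), or
#'   `NULL` to skip the survival stage.
#' @param output_dir Directory for all artifacts.
#' @param genome,gtf Optional genome FASTA + GTF pair instead of
#'   `sequences`.
#' @param min_tumor,min_pairs Cohort thresholds (defaults 3).
#' @param merge_map Optional label merge map (named list).
#' @param exclude_tissues Tissues excluded from grouping.
#' @param percent_convention Percent-difference convention
#'   (`"smaller"`/`"mean"`).
#' @param linkage Dendrogram linkage (default `"average"`).
#' @param alpha Family significance level (default 0.01).
#' @param bonferroni_wald,bonferroni_wilcoxon Bonferroni factors (3 and 64).
#' @param n_components PCA components (default 2).
#' @param km_horizon Kaplan-Meier horizon in years (default 10).
#' @param top_k Codons in the differential report (default 10).
#' @param rscu_reference Reference codon for the RSCU-shift regressions
#'   (default `"GGT"`; its synonymous partners are the regression targets).
#' @param seed Integer seed.
#' @return List of class `run_config`.
#' @export
run_config <- function(sequences = NULL, counts_dir, metadata, clinical = NULL,
                       output_dir, genome = NULL, gtf = NULL,
                       min_tumor = 3L, min_pairs = 3L, merge_map = NULL,
                       exclude_tissues = character(),
                       percent_convention = "smaller", linkage = "average",
                       alpha = 0.01, bonferroni_wald = 3L,
                       bonferroni_wilcoxon = 64L, n_components = 2L,
                       km_horizon = 10, top_k = 10L, rscu_reference = "GGT",
                       seed = 1L) {
  stopifnot(alpha > 0, alpha < 1)
  if (is.null(sequences) && (is.null(genome) || is.null(gtf))) {
    stop("provide either 'sequences' or both 'genome' and 'gtf'")
  }
  cfg <- list(sequences = sequences, genome = genome, gtf = gtf,
              counts_dir = counts_dir, metadata = metadata,
              clinical = clinical, output_dir = output_dir,
              min_tumor = as.integer(min_tumor),
              min_pairs = as.integer(min_pairs), merge_map = merge_map,
              exclude_tissues = exclude_tissues,
              percent_convention = percent_convention, linkage = linkage,
              alpha = alpha, bonferroni_wald = as.integer(bonferroni_wald),
              bonferroni_wilcoxon = as.integer(bonferroni_wilcoxon),
              n_components = as.integer(n_components),
              km_horizon = km_horizon, top_k = as.integer(top_k),
              rscu_reference = rscu_reference, seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML or JSON
#'
#' @param path Config file; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("unsupported config format: .", ext)
  do.call(run_config, raw)
}

validate_config <- function(config) {
  for (field in c("sequences", "genome", "gtf", "counts_dir", "metadata",
                  "clinical")) {
    p <- config[[field]]
    if (!is.null(p) && !file.exists(p)) {
      stop("config path for '", field, "' does not exist: ", p)
    }
  }
  invisible(config)
}

# ingest sequences per config and build count matrices
.pipeline_ingest <- function(config) {
  cds <- if (!is.null(config$sequences)) {
    read_cds_fasta(config$sequences)
  } else {
    extract_cds_from_gtf(config$genome, config$gtf)
  }
  build_count_matrices(select_primary_transcript(cds))
}

# read all count files needed, convert to TPM; returns genes x files matrix
.tpm_matrix <- function(config, file_ids, lens) {
  tpm <- vapply(file_ids, function(fid) {
    path <- file.path(config$counts_dir, paste0(fid, ".tsv"))
    if (!file.exists(path)) stop("missing count file: ", path)
    counts_to_tpm(read_htseq_counts(path), lens)
  }, numeric(length(lens)))
  rownames(tpm) <- names(lens)
  tpm
}

.write_manifest <- function(config, output_dir, files) {
  files <- sort(unique(files))
  hashes <- unname(tools::md5sum(file.path(output_dir, files)))
  manifest <- list(
    package = "oncocodon",
    version = as.character(utils::packageVersion("oncocodon")),
    config = config[setdiff(names(config), "output_dir")],
    outputs = stats::setNames(as.list(hashes), files))
  path <- file.path(output_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  path
}

#' Aggregate (median-sample) analysis stage
#'
#' Ingests sequences and cohort metadata, builds a median pseudo-sample per
#' tissue group, and writes: per-group codon and codon-pair usage tables,
#' the genomic (unweighted) baseline row, pairwise Euclidean distance
#' matrices, dendrograms (Newick), PCA scores, a differential-codon report
#' per cancer group against its tissue's normal group, and an aggregate MSE
#' table. A `manifest.json` with config and output hashes makes reruns
#' verifiable.
#'
#' @param config A `run_config`.
#' @return Invisible list of computed objects (`usage`, `pair_usage`,
#'   `groups`, `differential`, `mse_table`, `manifest`).
#' @export
run_aggregate <- function(config) {
  validate_config(config)
  set.seed(config$seed)
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- .pipeline_ingest(config)
  meta <- utils::read.delim(config$metadata, stringsAsFactors = FALSE)
  records <- filter_samples(meta)
  groups <- define_groups(records, merge_map = config$merge_map,
                          min_tumor = config$min_tumor,
                          exclude_tissues = config$exclude_tissues)
  if (nrow(groups) == 0L) stop("no tissue groups after filtering")
  all_files <- unique(unlist(groups$file_ids))
  tpm <- .tpm_matrix(config, all_files, counts$cds_length)

  usage <- t(vapply(seq_len(nrow(groups)), function(i) {
    med <- median_sample(tpm[, unlist(groups$file_ids[i]), drop = FALSE])
    weighted_usage(med, counts$codon)
  }, numeric(64L)))
  pair_usage <- t(vapply(seq_len(nrow(groups)), function(i) {
    med <- median_sample(tpm[, unlist(groups$file_ids[i]), drop = FALSE])
    weighted_pair_usage(med, counts$pair)
  }, numeric(4096L)))
  rownames(usage) <- rownames(pair_usage) <- groups$name
  usage <- rbind(usage, genomic = genomic_usage(counts$codon, 1000))
  pair_usage <- rbind(pair_usage,
                      genomic = genomic_usage(counts$pair, 1e6))

  files <- character()
  wr <- function(obj, name, id_column = "group") {
    write_matrix_tsv(obj, file.path(out_dir, name), id_column)
    files <<- c(files, name)
  }
  wr(usage, "usage_codon.tsv")
  wr(pair_usage, "usage_pair.tsv")
  dm_codon <- euclidean_matrix(usage)
  dm_pair <- euclidean_matrix(pair_usage)
  wr(dm_codon, "distance_codon.tsv")
  wr(dm_pair, "distance_pair.tsv")
  writeLines(hierarchical_cluster(dm_codon, config$linkage)$newick,
             file.path(out_dir, "dendrogram_codon.nwk"))
  writeLines(hierarchical_cluster(dm_pair, config$linkage)$newick,
             file.path(out_dir, "dendrogram_pair.nwk"))
  files <- c(files, "dendrogram_codon.nwk", "dendrogram_pair.nwk")
  pca <- pca_usage(usage, n_components = min(config$n_components,
                                             nrow(usage) - 1L))
  wr(pca$scores, "pca_codon.tsv")
  utils::write.table(
    data.frame(component = seq_along(pca$explained_variance),
               explained_variance = pca$explained_variance),
    file.path(out_dir, "pca_explained.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  files <- c(files, "pca_explained.tsv")

  # Table-1-style differential report: each cancer group vs its normal
  cancer <- groups[groups$kind == "cancer", , drop = FALSE]
  diffs <- list(); mse_rows <- list()
  for (i in seq_len(nrow(cancer))) {
    tis <- cancer$tissue_of_origin[i]
    nrow_idx <- which(groups$kind == "normal" &
                        groups$tissue_of_origin == tis)
    if (!length(nrow_idx)) next
    u_norm <- usage[groups$name[nrow_idx[1L]], ]
    u_can <- usage[cancer$name[i], ]
    top <- top_differential(u_norm, u_can, k = config$top_k,
                            convention = config$percent_convention)
    diffs[[length(diffs) + 1L]] <- rbind(
      data.frame(cancer = cancer$name[i], higher_in = "cancer",
                 codon = top$top_up$codon,
                 percent_difference = top$top_up$percent_difference,
                 stringsAsFactors = FALSE),
      data.frame(cancer = cancer$name[i], higher_in = "normal",
                 codon = top$top_down$codon,
                 percent_difference = top$top_down$percent_difference,
                 stringsAsFactors = FALSE))
    mse_rows[[length(mse_rows) + 1L]] <- data.frame(
      cancer = cancer$name[i], mse_codon = mse(u_norm, u_can),
      mse_pair = mse(pair_usage[groups$name[nrow_idx[1L]], ],
                     pair_usage[cancer$name[i], ]),
      stringsAsFactors = FALSE)
  }
  differential <- do.call(rbind, diffs)
  mse_table <- do.call(rbind, mse_rows)
  if (!is.null(differential)) {
    utils::write.table(differential, file.path(out_dir, "differential.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, "differential.tsv")
  }
  if (!is.null(mse_table)) {
    utils::write.table(mse_table, file.path(out_dir, "mse_aggregate.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, "mse_aggregate.tsv")
  }
  manifest <- .write_manifest(config, out_dir, files)
  invisible(list(usage = usage, pair_usage = pair_usage, groups = groups,
                 differential = differential, mse_table = mse_table,
                 manifest = manifest))
}

# Table-2-style per-cancer-type MSE summary with linear-interpolation
# quantiles
.mse_summary <- function(case_mse) {
  split_by <- split(case_mse, case_mse$cancer_type)
  rows <- lapply(names(split_by), function(ct) {
    v <- split_by[[ct]]$mse_codon
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(cancer_type = ct, mean = mean(v), min = min(v),
               p25 = q[1L], median = q[2L], p75 = q[3L], max = max(v),
               range = max(v) - min(v), n_patients = length(v),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Paired (per-patient) analysis stage
#'
#' Identifies matched tumor-normal pairs, computes per-case divergence
#' (codon-usage, pair-usage and TPM MSE), the per-cancer-type MSE summary
#' table (mean, min, quartiles, median, max, range, n), the case ranking
#' ("case 1" = highest codon-usage MSE), RSCU-shift regressions of the
#' reference codon's synonymous partners with Wald tests, the per-codon
#' paired Wilcoxon screen, and — when clinical data are configured — the
#' Kaplan-Meier comparison of the top vs bottom divergence quartiles.
#'
#' @param config A `run_config`.
#' @return Invisible list: `pairs`, `case_mse`, `mse_summary`,
#'   `rscu_regressions`, `wilcoxon`, `km` (or `NULL`), `manifest`.
#' @export
run_paired <- function(config) {
  validate_config(config)
  set.seed(config$seed)
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- .pipeline_ingest(config)
  meta <- utils::read.delim(config$metadata, stringsAsFactors = FALSE)
  records <- filter_samples(meta)
  groups <- define_groups(records, merge_map = config$merge_map,
                          min_tumor = config$min_tumor,
                          exclude_tissues = config$exclude_tissues)
  pairs <- find_pairs(records, groups, min_pairs = config$min_pairs)
  if (nrow(pairs) == 0L) {
    message("no matched pairs after cohort assembly; paired stage skipped")
    return(invisible(NULL))
  }
  pair_files <- unique(c(pairs$normal_file, pairs$tumor_file))
  tpm <- .tpm_matrix(config, pair_files, counts$cds_length)
  usage_by_file <- t(apply(tpm, 2L, weighted_usage, counts = counts$codon))
  pair_usage_by_file <- t(apply(tpm, 2L, weighted_pair_usage,
                                pairs = counts$pair))

  case_mse <- data.frame(
    case_id = pairs$case_id, cancer_type = pairs$cancer_type,
    mse_codon = vapply(seq_len(nrow(pairs)), function(i) {
      mse(usage_by_file[pairs$normal_file[i], ],
          usage_by_file[pairs$tumor_file[i], ])
    }, numeric(1)),
    mse_pair = vapply(seq_len(nrow(pairs)), function(i) {
      mse(pair_usage_by_file[pairs$normal_file[i], ],
          pair_usage_by_file[pairs$tumor_file[i], ])
    }, numeric(1)),
    mse_tpm = vapply(seq_len(nrow(pairs)), function(i) {
      mse(tpm[, pairs$normal_file[i]], tpm[, pairs$tumor_file[i]])
    }, numeric(1)),
    stringsAsFactors = FALSE)
  # "case 1" = the patient with the highest codon-usage MSE
  rank_order <- order(-case_mse$mse_codon, case_mse$case_id)
  case_mse$case_rank <- NA_integer_
  case_mse$case_rank[rank_order] <- seq_len(nrow(case_mse))
  mse_summary <- .mse_summary(case_mse)

  # RSCU-shift regressions: reference codon vs each synonymous partner
  fam <- codon_families()
  partners <- setdiff(names(fam)[fam == fam[config$rscu_reference]],
                      config$rscu_reference)
  deltas <- delta_rscu(pairs, usage_by_file)
  wide <- function(codon) {
    d <- deltas[deltas$codon == codon, , drop = FALSE]
    stats::setNames(d$delta, d$case_id)
  }
  dx <- wide(config$rscu_reference)
  regressions <- lapply(partners, function(p) {
    dy <- wide(p)
    shared <- intersect(names(dx), names(dy))
    t <- slope_wald_test(dx[shared], dy[shared],
                         bonferroni_m = config$bonferroni_wald,
                         alpha = config$alpha)
    data.frame(x_codon = config$rscu_reference, y_codon = p,
               slope = t$slope, r_squared = t$r_squared,
               p_value = t$p_value, n = t$n, threshold = t$threshold,
               significant = t$significant, stringsAsFactors = FALSE)
  })
  rscu_regressions <- do.call(rbind, regressions)

  wilcoxon <- paired_wilcoxon_screen(
    pairs, usage_by_file, bonferroni_m = config$bonferroni_wilcoxon,
    alpha = config$alpha)

  files <- character()
  wt <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files <<- c(files, name)
  }
  wt(pairs, "pairs.tsv")
  wt(case_mse, "case_mse.tsv")
  wt(mse_summary, "mse_summary.tsv")
  wt(rscu_regressions, "rscu_regressions.tsv")
  wt(wilcoxon, "wilcoxon_screen.tsv")

  km <- NULL
  if (!is.null(config$clinical)) {
    clin <- utils::read.delim(config$clinical, stringsAsFactors = FALSE)
    surv <- merge(case_mse, data.frame(case_id = clin$case_id,
                                       time = clin$time_years,
                                       event = as.logical(clin$event),
                                       stringsAsFactors = FALSE),
                  by = "case_id")
    if (nrow(surv) >= 8L) {
      qs <- quartile_split(surv, metric = "mse_codon")
      top_curve <- km_estimate(qs$top, horizon = config$km_horizon)
      bottom_curve <- km_estimate(qs$bottom, horizon = config$km_horizon)
      km <- compare_groups(top_curve, bottom_curve)
      km_tab <- rbind(
        data.frame(group = "top", time = top_curve$time,
                   surv = top_curve$surv, lower = top_curve$lower,
                   upper = top_curve$upper),
        data.frame(group = "bottom", time = bottom_curve$time,
                   surv = bottom_curve$surv, lower = bottom_curve$lower,
                   upper = bottom_curve$upper))
      wt(km_tab, "km_curves.tsv")
      wt(km$overlap_by_year, "km_overlap.tsv")
      summary_json <- list(
        median_top = km$median_top, median_bottom = km$median_bottom,
        n_top = top_curve$n, n_bottom = bottom_curve$n)
      jsonlite::write_json(summary_json,
                           file.path(out_dir, "km_summary.json"),
                           auto_unbox = TRUE, digits = NA, null = "null")
      files <- c(files, "km_summary.json")
    } else {
      message("fewer than 8 cases with clinical data; survival stage skipped")
    }
  }
  manifest <- .write_manifest(config, out_dir, files)
  invisible(list(pairs = pairs, case_mse = case_mse,
                 mse_summary = mse_summary,
                 rscu_regressions = rscu_regressions, wilcoxon = wilcoxon,
                 km = km, usage_by_file = usage_by_file,
                 manifest = manifest))
}

#' Full pipeline run
#'
#' Runs the aggregate stage into `output_dir/aggregate/` and the paired
#' stage into `output_dir/paired/`, then writes a combined top-level
#' manifest of both stages' outputs.
#'
#' @param config A `run_config`.
#' @return Invisible list: `aggregate`, `paired`, `manifest`.
#' @export
run_all <- function(config) {
  validate_config(config)
  base <- config$output_dir
  dir.create(base, recursive = TRUE, showWarnings = FALSE)
  cfg_a <- config; cfg_a$output_dir <- file.path(base, "aggregate")
  cfg_p <- config; cfg_p$output_dir <- file.path(base, "paired")
  agg <- run_aggregate(cfg_a)
  par <- run_paired(cfg_p)
  rel <- c(file.path("aggregate",
                     setdiff(list.files(cfg_a$output_dir), "manifest.json")),
           if (!is.null(par)) file.path(
             "paired", setdiff(list.files(cfg_p$output_dir),
                               "manifest.json")))
  manifest <- .write_manifest(config, base, rel)
  invisible(list(aggregate = agg, paired = par, manifest = manifest))
}

#' Generate a complete synthetic input set for the pipeline
#'
#' Convenience wrapper around the synthetic generator: writes the gene
#' FASTA, count files, metadata, truth record and clinical table under
#' `dir`, and returns a ready-to-run [run_config()] pointing at them.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Directory for the generated inputs.
#' @param output_dir Output directory for the returned config (default
#'   `file.path(dir, "results")`).
#' @return A `run_config`.
#' @export
simulate_inputs <- function(spec, dir,
                            output_dir = file.path(dir, "results")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fasta <- file.path(dir, "genes.fa")
  genes <- generate_genes(spec, path = fasta)
  cohort <- generate_cohort(spec, genes, dir)
  clinical <- file.path(dir, "clinical.tsv")
  generate_survival(spec, cohort$truth, path = clinical)
  run_config(sequences = fasta, counts_dir = cohort$counts_dir,
             metadata = cohort$metadata_path, clinical = clinical,
             output_dir = output_dir, seed = spec$seed)
}
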