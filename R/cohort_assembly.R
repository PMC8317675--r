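#' Apply the sample-selection filters to a cohort metadata table
#'
#' Retains only "primary tumor" and "solid tissue normal" samples from
#' patients with no prior treatment. Sample-type labels are matched
#' case-insensitively.
#'
#' @param records Data frame with columns `file_id`, `case_id`,
#'   `sample_type`, `tissue_of_origin`, `primary_diagnosis`,
#'   `prior_treatment` (logical).
#' @return The retained records, with an `"exclusions"` attribute: a named
#'   integer vector tallying drops by reason (`sample_type`,
#'   `prior_treatment`).
#' @export
filter_samples <- function(records) {
  required <- c("file_id", "case_id", "sample_type", "tissue_of_origin",
                "primary_diagnosis", "prior_treatment")
  missing <- setdiff(required, names(records))
  if (length(missing)) stop("metadata lacks columns: ",
                            paste(missing, collapse = ", "))
  if (anyDuplicated(records$file_id)) stop("file_id values are not unique")
  st <- tolower(trimws(records$sample_type))
  keep_type <- st %in% c("primary tumor", "solid tissue normal")
  # a sample-type drop is tallied first; prior treatment only among the rest
  keep_prior <- !as.logical(records$prior_treatment)
  out <- records[keep_type & keep_prior, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusions") <- c(
    sample_type = sum(!keep_type),
    prior_treatment = sum(keep_type & !keep_prior))
  out
}

#' Default label merges and tissue exclusions
#'
#' Ships the package's default GDC-style label merges (sub-site lung labels
#' onto "lung", esophageal SCC subtypes onto one diagnosis) and the default
#' tissue exclusion list (heterogeneous thyroid, normal-free brain) as a
#' config object. These are data, not code: pass your own file for other
#' cohorts.
#'
#' @param path JSON config with fields `merge_map` and `exclude_tissues`;
#'   defaults to the file shipped with the package.
#' @return List with elements `merge_map` (named list) and
#'   `exclude_tissues` (character).
#' @export
default_merge_config <- function(path = system.file(
  "extdata", "default_merge_map.json", package = "oncocodon")) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(merge_map = as.list(cfg$merge_map),
       exclude_tissues = as.character(cfg$exclude_tissues))
}

apply_merge_map <- function(labels, map) {
  if (is.null(map) || length(map) == 0L) return(labels)
  hit <- labels %in% names(map)
  labels[hit] <- unlist(map)[labels[hit]]
  labels
}

#' Group filtered samples into normal-tissue and cancer types
#'
#' Normal groups are keyed by (merged) tissue of origin; cancer groups by
#' (merged) tissue of origin and diagnosis. Cancer groups are retained only
#' if they hold at least `min_tumor` tumor samples and a normal group of the
#' same tissue exists. Per tissue with more than one kept cancer subtype, an
#' additional "aggregate" group is emitted as the union of the kept
#' subtypes.
#'
#' @param records Filtered sample records (see [filter_samples()]).
#' @param merge_map Named list/vector mapping raw labels to merged labels,
#'   applied to both tissue and diagnosis labels before grouping. May be
#'   empty.
#' @param min_tumor Minimum tumor samples for a cancer group (default 3).
#' @param exclude_tissues Tissues to drop entirely (e.g. heterogeneous
#'   tissues excluded from analysis); config-driven, empty by default.
#' @return Data frame of class `tissue_groups` with columns `name`, `kind`
#'   (`"normal"`/`"cancer"`), `tissue_of_origin`, `diagnosis` (`NA` for
#'   normal and aggregate rows use the pooled label), `n`, and list-column
#'   `file_ids`.
#' @export
define_groups <- function(records, merge_map = NULL, min_tumor = 3L,
                          exclude_tissues = character()) {
  tissue <- apply_merge_map(records$tissue_of_origin, merge_map)
  diagnosis <- apply_merge_map(records$primary_diagnosis, merge_map)
  keep <- !(tissue %in% exclude_tissues)
  records <- records[keep, , drop = FALSE]
  tissue <- tissue[keep]; diagnosis <- diagnosis[keep]
  st <- tolower(trimws(records$sample_type))

  rows <- list()
  is_norm <- st == "solid tissue normal"
  for (tis in sort(unique(tissue[is_norm]))) {
    ids <- records$file_id[is_norm & tissue == tis]
    rows[[length(rows) + 1L]] <- data.frame(
      name = paste0("normal ", tis), kind = "normal", tissue_of_origin = tis,
      diagnosis = NA_character_, n = length(ids), stringsAsFactors = FALSE)
    rows[[length(rows)]]$file_ids <- I(list(ids))
  }
  normal_tissues <- sort(unique(tissue[is_norm]))

  is_tum <- st == "primary tumor"
  key <- paste(tissue, diagnosis, sep = "\r")
  kept_by_tissue <- list()
  for (k in sort(unique(key[is_tum]))) {
    sel <- is_tum & key == k
    tis <- tissue[sel][1L]; dia <- diagnosis[sel][1L]
    ids <- records$file_id[sel]
    if (length(ids) < min_tumor) next
    if (!(tis %in% normal_tissues)) next
    rows[[length(rows) + 1L]] <- data.frame(
      name = paste0(dia, " - ", tis), kind = "cancer",
      tissue_of_origin = tis, diagnosis = dia, n = length(ids),
      stringsAsFactors = FALSE)
    rows[[length(rows)]]$file_ids <- I(list(ids))
    kept_by_tissue[[tis]] <- c(kept_by_tissue[[tis]], list(ids))
  }
  # aggregate = union of kept subtype groups, one per tissue with >1 subtype
  for (tis in names(kept_by_tissue)) {
    if (length(kept_by_tissue[[tis]]) < 2L) next
    ids <- sort(unique(unlist(kept_by_tissue[[tis]])))
    rows[[length(rows) + 1L]] <- data.frame(
      name = paste0("aggregate - ", tis), kind = "cancer",
      tissue_of_origin = tis, diagnosis = "aggregate", n = length(ids),
      stringsAsFactors = FALSE)
    rows[[length(rows)]]$file_ids <- I(list(ids))
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(name = character(), kind = character(),
                      tissue_of_origin = character(),
                      diagnosis = character(), n = integer(),
                      stringsAsFactors = FALSE)
    out$file_ids <- I(list())
  }
  rownames(out) <- NULL
  class(out) <- c("tissue_groups", "data.frame")
  out
}

#' Identify matched normal-tumor pairs per case
#'
#' A paired case is a patient contributing exactly one retained solid tissue
#' normal file and one retained primary tumor file within a given cancer
#' type. Cases with multiple candidate files on either side are resolved
#' deterministically to the lexicographically smallest `file_id`, with a
#' warning. Cancer types with fewer than `min_pairs` pairs are excluded.
#'
#' @param records Filtered sample records.
#' @param groups Output of [define_groups()]. Aggregate groups are skipped
#'   (their subtypes already contribute their pairs).
#' @param min_pairs Minimum pairs for a cancer type to enter paired analysis
#'   (default 3).
#' @return Data frame with columns `case_id`, `normal_file`, `tumor_file`,
#'   `cancer_type`.
#' @export
find_pairs <- function(records, groups, min_pairs = 3L) {
  st <- tolower(trimws(records$sample_type))
  normal_groups <- groups[groups$kind == "normal", , drop = FALSE]
  cancer_groups <- groups[groups$kind == "cancer" &
                            groups$diagnosis != "aggregate", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(cancer_groups))) {
    tis <- cancer_groups$tissue_of_origin[i]
    norm_ids <- unlist(normal_groups$file_ids[
      normal_groups$tissue_of_origin == tis])
    tum_ids <- unlist(cancer_groups$file_ids[i])
    tum <- records[records$file_id %in% tum_ids, , drop = FALSE]
    norm <- records[records$file_id %in% norm_ids, , drop = FALSE]
    shared <- intersect(unique(tum$case_id), unique(norm$case_id))
    if (length(shared) == 0L) next
    pick <- function(df, case) {
      ids <- sort(df$file_id[df$case_id == case])
      if (length(ids) > 1L) {
        warning("case ", case, ": multiple candidate files; keeping ", ids[1L])
      }
      ids[1L]
    }
    pairs <- data.frame(
      case_id = sort(shared),
      normal_file = vapply(sort(shared), pick, "", df = norm),
      tumor_file = vapply(sort(shared), pick, "", df = tum),
      cancer_type = cancer_groups$name[i],
      stringsAsFactors = FALSE)
    if (nrow(pairs) < min_pairs) next
    out[[length(out) + 1L]] <- pairs
  }
  if (length(out) == 0L) {
    return(data.frame(case_id = character(), normal_file = character(),
                      tumor_file = character(), cancer_type = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
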