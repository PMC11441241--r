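#' @title Intensity tables and the preprocessing pipeline
#' @description Raw identification exports enter as a records data frame
#'   (one row per lipid ion: `name`, `adduct`, `grade`, `ppm`, then one
#'   area column per injection) plus a sample-metadata data frame. The
#'   pipeline turns them into a stage-tagged `lipid_table`:
#'   merge adducts -> blank filter -> internal-standard normalization ->
#'   median normalization -> presence filter. Stages only advance in that
#'   order; no operation ever imputes a missing value.
#' @name preprocess
NULL

STAGES <- c("raw", "merged", "blank_filtered", "std_normalized",
            "median_normalized", "presence_filtered",
            "pca_filtered", "completed", "batch_adjusted")

#' Construct an intensity table
#'
#' @param values Numeric species-by-samples matrix; `NA` marks a
#'   non-detection. Zero areas are coerced to `NA` (a zero peak area is a
#'   non-detection in this data type). Negative values are rejected.
#' @param species Species annotation data frame as from [species_table()];
#'   rows must match `rownames(values)`.
#' @param samples Sample metadata data frame with columns `sample_id`,
#'   `condition` (`"control"`/`"hypoxia"`), `set_id`, `replicate`,
#'   `is_blank`; rows must match `colnames(values)`.
#' @param stage Stage tag, one of the pipeline stages.
#' @return An object of class `lipid_table`.
#' @export
lipid_table <- function(values, species, samples, stage = "merged") {
  stopifnot(is.matrix(values), stage %in% STAGES)
  if (any(values < 0, na.rm = TRUE)) {
    condition_error("intensity values must be non-negative",
                    "lipidflux_data_error")
  }
  values[!is.na(values) & values == 0] <- NA_real_
  stopifnot(identical(rownames(values), species$name),
            identical(colnames(values), samples$sample_id))
  nb <- samples[!samples$is_blank, , drop = FALSE]
  key <- paste(nb$condition, nb$set_id, nb$replicate)
  if (anyDuplicated(key)) {
    condition_error("(condition, set_id, replicate) must be unique among non-blank samples",
                    "lipidflux_data_error")
  }
  structure(list(values = values, species = species, samples = samples,
                 stage = stage, log = NULL),
            class = "lipid_table")
}

#' @export
print.lipid_table <- function(x, ...) {
  cat(sprintf("<lipid_table> %d species x %d samples  [stage: %s]\n",
              nrow(x$values), ncol(x$values), x$stage))
  tab <- table(x$samples$condition[!x$samples$is_blank])
  cat("  samples:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      sprintf("(+%d blanks)\n", sum(x$samples$is_blank)))
  cat("  missing:", sprintf("%.1f%%", 100 * mean(is.na(x$values))), "\n")
  invisible(x)
}

#' @export
dim.lipid_table <- function(x) dim(x$values)

advance_stage <- function(table, to) {
  from <- match(table$stage, STAGES)
  target <- match(to, STAGES)
  if (is.na(target) || target <= from) {
    condition_error(sprintf(
      "stage may only advance along %s; cannot move '%s' -> '%s'",
      paste(STAGES, collapse = " > "), table$stage, to),
      "lipidflux_stage_error")
  }
  table$stage <- to
  table
}

append_log <- function(table, rule, species, statistic, action = "removed") {
  if (length(species) == 0L) return(table)
  entry <- data.frame(rule = rule, species = species,
                      statistic = as.numeric(statistic), action = action,
                      stringsAsFactors = FALSE)
  table$log <- rbind(table$log, entry)
  table
}

drop_species <- function(table, keep) {
  table$values <- table$values[keep, , drop = FALSE]
  table$species <- table$species[keep, , drop = FALSE]
  rownames(table$species) <- NULL
  table
}

#' Filter raw records on identification quality
#'
#' Keeps records whose identification grade is in `grades` and whose
#' absolute mass error does not exceed `max_ppm` (default: the 5 ppm
#' precursor search tolerance).
#'
#' @param records Records data frame (columns `name`, `adduct`, `grade`,
#'   `ppm`, then area columns).
#' @param grades Character set of acceptable grades, e.g. `c("A", "B")`.
#' @param max_ppm Maximum absolute ppm error.
#' @return The filtered records data frame.
#' @export
quality_filter <- function(records, grades = c("A", "B"), max_ppm = 5) {
  stopifnot(length(grades) >= 1L)
  if (nrow(records) == 0L) return(records)
  keep <- records$grade %in% grades & abs(records$ppm) <= max_ppm
  records[keep, , drop = FALSE]
}

#' Average technical replicate injections
#'
#' The acquisition injects each biological replicate more than once; area
#' columns named `<sample_id>.t<k>` are averaged (over non-missing
#' injections) into one column per biological replicate before any
#' statistics.
#'
#' @param records Records data frame whose area columns follow the
#'   `<sample_id>.t<k>` convention (columns without the suffix pass
#'   through).
#' @return Records data frame with one area column per biological sample.
#' @export
average_technical_replicates <- function(records) {
  meta_cols <- c("name", "adduct", "grade", "ppm")
  area_cols <- setdiff(names(records), meta_cols)
  base <- sub("\\.t[0-9]+$", "", area_cols)
  out <- records[meta_cols]
  for (b in unique(base)) {
    cols <- area_cols[base == b]
    m <- as.matrix(records[cols])
    out[[b]] <- rowMeans(m, na.rm = TRUE)
    out[[b]][!is.finite(out[[b]])] <- NA_real_
  }
  out
}

#' Merge adduct rows into one row per species
#'
#' Identical lipids detected as different ion adducts are summed per
#' sample: `missing + missing = missing`, `missing + x = x`. Names are
#' canonicalized first, so chain-order variants of the same species merge
#' too. Total non-missing area is conserved.
#'
#' @param records Quality-filtered records data frame.
#' @param samples Sample metadata; `sample_id` must match the area columns.
#' @param vocabulary Class vocabulary for name parsing.
#' @return A `lipid_table` at stage `"merged"`.
#' @export
merge_adducts <- function(records, samples, vocabulary = lipid_vocabulary()) {
  meta_cols <- c("name", "adduct", "grade", "ppm")
  area_cols <- setdiff(names(records), meta_cols)
  stopifnot(setequal(area_cols, samples$sample_id))
  canon <- tryCatch(canonical_names(records$name, vocabulary),
                    lipidflux_error = function(e) {
                      bad <- which(vapply(records$name, function(nm) {
                        inherits(tryCatch(parse_shorthand(nm, vocabulary),
                                          error = function(e2) e2), "error")
                      }, logical(1L)))
                      condition_error(sprintf(
                        "unparseable lipid name(s) in rows: %s (e.g. '%s': %s)",
                        paste(bad, collapse = ", "),
                        records$name[bad[1L]], conditionMessage(e)),
                        "lipidflux_parse_error")
                    })
  areas <- as.matrix(records[samples$sample_id])
  groups <- split(seq_len(nrow(records)), canon)
  nms <- names(groups)
  values <- matrix(NA_real_, nrow = length(groups), ncol = ncol(areas),
                   dimnames = list(nms, samples$sample_id))
  for (i in seq_along(groups)) {
    sub <- areas[groups[[i]], , drop = FALSE]
    s <- colSums(sub, na.rm = TRUE)
    s[colSums(!is.na(sub)) == 0L] <- NA_real_
    values[i, ] <- s
  }
  lipid_table(values, species_table(nms, vocabulary), samples,
              stage = "merged")
}

#' Exclude species insufficiently above blank controls
#'
#' A species is treated as contamination and removed unless its mean
#' intensity over biological samples is at least `min_fold` times its mean
#' intensity over blank runs. Species absent from the blanks (or with zero
#' blank mean) are retained. Removed species are reported in the table's
#' filter log with their sample/blank ratios.
#'
#' @param table A `lipid_table` of biological samples at stage `"merged"`.
#' @param blanks A `lipid_table` of blank runs sharing the species axis
#'   (missing species allowed).
#' @param min_fold Required fold difference (> 1), default 5.
#' @return The filtered `lipid_table` at stage `"blank_filtered"`.
#' @export
blank_filter <- function(table, blanks, min_fold = 5) {
  stopifnot(inherits(table, "lipid_table"), min_fold > 1)
  blank_values <- if (inherits(blanks, "lipid_table")) blanks$values else blanks
  sample_mean <- rowMeans(table$values, na.rm = TRUE)
  idx <- match(rownames(table$values), rownames(blank_values))
  blank_mean <- rep(NA_real_, nrow(table$values))
  has_blank <- !is.na(idx)
  if (any(has_blank)) {
    bm <- rowMeans(blank_values[idx[has_blank], , drop = FALSE], na.rm = TRUE)
    bm[!is.finite(bm)] <- NA_real_
    blank_mean[has_blank] <- bm
  }
  ratio <- sample_mean / blank_mean
  keep <- is.na(blank_mean) | blank_mean == 0 |
    (!is.na(ratio) & ratio >= min_fold)
  out <- append_log(table, "blank_filter",
                    rownames(table$values)[!keep], ratio[!keep])
  out <- drop_species(out, keep)
  advance_stage(out, "blank_filtered")
}

#' Normalize to class-matched internal standards
#'
#' Every species is divided, per sample, by the area of the spiked internal
#' standard of its lipid class (one labeled standard per class, spiked
#' before extraction). Standards themselves are removed from the output
#' species axis. A class with no mapped standard is a configuration error;
#' a standard missing in any sample is an error naming the samples.
#'
#' @param table A `lipid_table` (stage `"blank_filtered"` or earlier
#'   stages are rejected by the stage guard on output).
#' @param standard_map Data frame with columns `class_code`,
#'   `standard_name` (a shorthand name present in the table) and optionally
#'   `surrogate_for` fallbacks already resolved into rows.
#' @return The normalized `lipid_table` at stage `"std_normalized"`.
#' @export
internal_standard_normalize <- function(table, standard_map) {
  stopifnot(inherits(table, "lipid_table"))
  std_names <- canonical_names(standard_map$standard_name)
  classes_needed <- unique(table$species$class_code[
    !table$species$name %in% std_names])
  unmapped <- setdiff(classes_needed, standard_map$class_code)
  if (length(unmapped) > 0L) {
    condition_error(sprintf("no internal standard mapped for class(es): %s",
                            paste(unmapped, collapse = ", ")),
                    "lipidflux_config_error")
  }
  std_rows <- match(std_names, rownames(table$values))
  if (anyNA(std_rows)) {
    condition_error(sprintf("standard species not found in table: %s",
                            paste(std_names[is.na(std_rows)], collapse = ", ")),
                    "lipidflux_config_error")
  }
  std_mat <- table$values[std_rows, , drop = FALSE]
  if (anyNA(std_mat)) {
    bad <- colnames(std_mat)[colSums(is.na(std_mat)) > 0L]
    condition_error(sprintf("internal standard missing in sample(s): %s",
                            paste(bad, collapse = ", ")),
                    "lipidflux_data_error")
  }
  denom <- std_mat[match(table$species$class_code, standard_map$class_code), ,
                   drop = FALSE]
  out <- table
  out$values <- table$values / denom
  is_std <- rownames(out$values) %in% std_names
  out <- append_log(out, "internal_standard", rownames(out$values)[is_std],
                    NA_real_, action = "standard_removed")
  out <- drop_species(out, !is_std)
  advance_stage(out, "std_normalized")
}

#' Median normalization across samples
#'
#' Each sample is rescaled so that all per-sample medians (over non-missing
#' values) equal the reference, the median of the per-sample medians. The
#' operation is idempotent.
#'
#' @param table A `lipid_table`; every sample must have at least one
#'   non-missing value.
#' @return The normalized `lipid_table` at stage `"median_normalized"`.
#' @export
median_normalize <- function(table) {
  stopifnot(inherits(table, "lipid_table"))
  meds <- apply(table$values, 2L, stats::median, na.rm = TRUE)
  if (anyNA(meds)) {
    condition_error(sprintf("sample(s) with no non-missing values: %s",
                            paste(colnames(table$values)[is.na(meds)],
                                  collapse = ", ")),
                    "lipidflux_data_error")
  }
  reference <- stats::median(meds)
  out <- table
  out$values <- sweep(table$values, 2L, reference / meds, `*`)
  advance_stage(out, "median_normalized")
}

detection_matrix <- function(table) !is.na(table$values)

#' Presence filter across sets and conditions
#'
#' Retains a species only if it was detected in at least one sample of
#' each set (when `require_both_sets`) and in at least `min_frac` of the
#' samples within at least one condition (conditions pooled over sets).
#' Blank samples are ignored.
#'
#' @param table A `lipid_table`.
#' @param min_frac Minimum detection fraction within a condition
#'   (default 0.5).
#' @param require_both_sets Require detection in every set (default TRUE).
#' @return The filtered `lipid_table` at stage `"presence_filtered"`.
#' @export
presence_filter <- function(table, min_frac = 0.5, require_both_sets = TRUE) {
  stopifnot(inherits(table, "lipid_table"))
  bio <- !table$samples$is_blank
  det <- detection_matrix(table)[, bio, drop = FALSE]
  meta <- table$samples[bio, , drop = FALSE]
  keep <- rep(TRUE, nrow(det))
  if (require_both_sets) {
    for (s in unique(meta$set_id)) {
      keep <- keep & rowSums(det[, meta$set_id == s, drop = FALSE]) >= 1L
    }
  }
  best_frac <- rep(0, nrow(det))
  for (cond in unique(meta$condition)) {
    frac <- rowMeans(det[, meta$condition == cond, drop = FALSE])
    best_frac <- pmax(best_frac, frac)
  }
  keep <- keep & best_frac >= min_frac
  out <- append_log(table, "presence_filter",
                    rownames(table$values)[!keep], best_frac[!keep])
  out <- drop_species(out, keep)
  advance_stage(out, "presence_filtered")
}
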