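#' @title End-to-end pipeline orchestration
#' @description One call from raw identification exports to the full
#'   result set: quality filter, technical-replicate averaging, adduct
#'   merging, blank exclusion, internal-standard and median
#'   normalization, presence filtering, then the PCA branch (50%-of-all-
#'   samples filter, completion, batch adjustment, PCA, spanning species,
#'   class enrichment) and the differential branch (exclusive species,
#'   multiple t-tests, double-bond and acyl profiles).
#' @name pipeline
NULL

#' Run the full analysis pipeline
#'
#' @param records Raw records data frame (see [merge_adducts()]); area
#'   columns may carry `.t<k>` technical-replicate suffixes.
#' @param samples Biological sample metadata.
#' @param blank_records Blank-run records data frame (same layout; area
#'   columns are blank run ids), or NULL to skip blank filtering.
#' @param standard_map Internal-standard map (class_code, standard_name),
#'   or NULL to skip standard normalization.
#' @param grades,max_ppm Quality-filter settings.
#' @param blank_min_fold Blank exclusion fold (default 5).
#' @param presence_min_frac,require_both_sets Presence-filter settings.
#' @param pca_min_frac PCA-branch presence fraction over all samples.
#' @param completion Missing-value completion method for the PCA branch.
#' @param pca_dims Number of PCA dimensions to compute.
#' @param spanning_fold Contribution multiple defining spanning species.
#' @param alpha Significance level for enrichment direction calls.
#' @param profile_class Class for the double-bond and acyl profiles.
#' @return A `lipid_pipeline` list: the stage tables, `pca`, `separating_dim`,
#'   `spanning`, `enrichment`, `exclusive`, `differential`,
#'   `double_bond_profile`, `acyl_profile`, `filter_log`, and a `summary`
#'   of per-stage species counts.
#' @export
run_pipeline <- function(records, samples, blank_records = NULL,
                         standard_map = NULL,
                         grades = c("A", "B"), max_ppm = 5,
                         blank_min_fold = 5,
                         presence_min_frac = 0.5, require_both_sets = TRUE,
                         pca_min_frac = 0.5,
                         completion = "half_min",
                         pca_dims = 5L,
                         spanning_fold = 2,
                         alpha = 0.05,
                         profile_class = "TG") {
  vocabulary <- lipid_vocabulary()
  counts <- c(raw_records = nrow(records))

  rec <- quality_filter(records, grades = grades, max_ppm = max_ppm)
  counts["quality_filtered_records"] <- nrow(rec)
  rec <- average_technical_replicates(rec)

  tab <- merge_adducts(rec, samples, vocabulary)
  counts["merged_species"] <- nrow(tab$values)

  if (!is.null(blank_records) && nrow(blank_records) > 0L) {
    brec <- average_technical_replicates(
      quality_filter(blank_records, grades = grades, max_ppm = max_ppm))
    blank_ids <- setdiff(names(brec), c("name", "adduct", "grade", "ppm"))
    blank_samples <- data.frame(sample_id = blank_ids, condition = "blank",
                                set_id = "blank", replicate = seq_along(blank_ids),
                                is_blank = TRUE, stringsAsFactors = FALSE)
    blanks <- merge_adducts(brec, blank_samples, vocabulary)
    tab <- blank_filter(tab, blanks, min_fold = blank_min_fold)
  } else {
    tab <- advance_stage(tab, "blank_filtered")
  }
  counts["blank_filtered_species"] <- nrow(tab$values)

  if (!is.null(standard_map)) {
    tab <- internal_standard_normalize(tab, standard_map)
  } else {
    tab <- advance_stage(tab, "std_normalized")
  }
  tab <- median_normalize(tab)
  tab <- presence_filter(tab, min_frac = presence_min_frac,
                         require_both_sets = require_both_sets)
  counts["presence_filtered_species"] <- nrow(tab$values)

  # PCA branch
  pca_tab <- pca_presence_filter(tab, min_frac = pca_min_frac)
  counts["pca_species"] <- nrow(pca_tab$values)
  pca_tab <- complete_missing(pca_tab, method = completion)
  ba <- batch_adjust(pca_tab)
  pca_dims <- min(pca_dims,
                  sum(!ba$table$samples$is_blank) - 1L,
                  nrow(ba$table$values))
  pca <- run_pca(ba$table, dims = pca_dims)
  sep_dim <- separating_dimension(pca)
  spanning <- spanning_species(pca, dim = sep_dim, fold = spanning_fold)
  enrichment <- class_enrichment(spanning, pca$species, alpha = alpha)

  # differential branch
  exclusive <- exclusive_species(tab)
  differential <- multi_ttest(tab)
  dbp <- double_bond_profile(tab, profile_class)
  ap <- tryCatch(acyl_profile(tab, profile_class),
                 lipidflux_undefined_query_error = function(e) NULL)

  counts["spanning_species"] <- length(spanning)
  counts["hypoxia_exclusive"] <- length(exclusive$hypoxia)
  counts["significant_units"] <- sum(differential$p_adj < alpha, na.rm = TRUE)

  structure(list(
    table = tab, pca_table = ba$table, batch_model = ba$model,
    pca = pca, separating_dim = sep_dim, spanning = spanning,
    enrichment = enrichment, exclusive = exclusive,
    differential = differential, double_bond_profile = dbp,
    acyl_profile = ap,
    filter_log = rbind(tab$log, ba$table$log),
    summary = counts), class = "lipid_pipeline")
}

#' @export
print.lipid_pipeline <- function(x, ...) {
  cat("<lipid_pipeline>\n")
  for (nm in names(x$summary)) {
    cat(sprintf("  %-28s %d\n", nm, x$summary[[nm]]))
  }
  cat(sprintf("  separating dimension: PC%d (%.1f%% variance)\n",
              x$separating_dim, 100 * x$pca$explained_frac[x$separating_dim]))
  sig <- x$enrichment[x$enrichment$direction != "none", , drop = FALSE]
  if (nrow(sig)) {
    cat("  enriched/depleted classes:",
        paste(sprintf("%s (%s, p=%.2g)", sig$class_code, sig$direction,
                      sig$p_value), collapse = ", "), "\n")
  }
  invisible(x)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write all pipeline outputs to a directory
#'
#' Emits stage matrices, scores/loadings/contributions, the enrichment
#' and differential tables, profiles, the machine-readable filter log,
#' and a provenance block (package version, seed if given, per-stage
#' counts).
#'
#' @param result A `lipid_pipeline`.
#' @param dir Output directory (created if needed).
#' @param seed Seed to record in the provenance block (optional).
#' @return Invisibly, the paths written.
#' @export
write_pipeline_outputs <- function(result, dir, seed = NA_integer_) {
  stopifnot(inherits(result, "lipid_pipeline"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  mat_df <- function(m) cbind(data.frame(species = rownames(m)),
                              as.data.frame(m, check.names = FALSE))
  write_tsv(mat_df(result$table$values), p("intensities_filtered.tsv"))
  write_tsv(mat_df(result$pca_table$values), p("intensities_pca.tsv"))
  write_tsv(cbind(sample = rownames(result$pca$scores),
                  as.data.frame(result$pca$scores)), p("pca_scores.tsv"))
  write_tsv(mat_df(result$pca$loadings), p("pca_loadings.tsv"))
  write_tsv(mat_df(result$pca$contributions), p("pca_contributions.tsv"))
  write_tsv(data.frame(dim = seq_along(result$pca$explained_frac),
                       explained_frac = result$pca$explained_frac),
            p("pca_explained.tsv"))
  write_tsv(result$enrichment, p("enrichment.tsv"))
  write_tsv(result$differential, p("differential.tsv"))
  write_tsv(result$double_bond_profile, p("double_bond_profile.tsv"))
  if (!is.null(result$acyl_profile)) {
    write_tsv(mat_df(result$acyl_profile), p("acyl_profile.tsv"))
  }
  if (!is.null(result$filter_log)) {
    write_tsv(result$filter_log, p("filter_log.tsv"))
  }
  prov <- c(sprintf("package_version\t%s",
                    as.character(utils::packageVersion("lipidflux"))),
            sprintf("seed\t%s", seed),
            sprintf("%s\t%d", names(result$summary), result$summary))
  writeLines(prov, p("provenance.tsv"))
  invisible(list.files(dir, full.names = TRUE))
}
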