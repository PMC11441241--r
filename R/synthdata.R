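#' @title Synthetic lipid-identification exports with planted ground truth
#' @description Emulates the input contract of the preprocessing stage —
#'   a two-set (batch), two-condition design with 9 biological replicates
#'   per condition per set, log-normal abundances with class-level
#'   baselines, intensity-dependent dropout, multiplicative batch effects,
#'   blank contamination, spiked internal standards, adduct-split rows,
#'   technical replicate injections, and planted hypoxia effects (a TG
#'   abundance increase, condition-exclusive 16:4-containing species) — so
#'   that every later stage can be tested for parameter recovery.
#' @name synthdata
NULL

default_class_counts <- c(
  TG = 140, DG = 25, MGDG = 20, DGDG = 15,
  PA = 20, PC = 40, PE = 36, PG = 15, PI = 12, LPC = 12, LPE = 8,
  Cer = 26, HexCer = 16, SM = 18,
  SE = 14, AHexSit = 10, PR = 8
)

default_baselines <- c(
  TG = 19, DG = 16.5, MGDG = 17, DGDG = 16,
  PA = 16, PC = 18, PE = 17.5, PG = 15.5, PI = 15, LPC = 14.5, LPE = 14,
  Cer = 15, HexCer = 14.5, SM = 15.5,
  SE = 15, AHexSit = 14, PR = 13.5
)

default_effects <- data.frame(
  class_code = c("TG", "PA", "PC", "LPC", "MGDG"),
  log2_fold = c(0.6, 0.4, -0.4, -0.4, -0.3),
  proportion = c(0.6, 0.4, 0.5, 0.5, 0.4),
  stringsAsFactors = FALSE
)

#' Configuration of the synthetic-data generator
#'
#' Defaults reproduce the study design the pipeline targets: two
#' independently grown sets, nine control and nine waterlogged (hypoxia)
#' replicates per set, two injections per biological replicate, roughly
#' 440 species across the major classes with glycerolipids plus
#' glycerophospholipids near 78% of the inventory, a TG increase of
#' log2-fold 0.6 on 60% of TG species under hypoxia, and 11
#' hypoxia-exclusive species (9 TG + 2 PE), all carrying a 16:4 fatty
#' acyl.
#'
#' @param n_sets Number of growth sets (batches).
#' @param n_reps Biological replicates per condition per set.
#' @param n_tech_reps Injections per biological replicate.
#' @param class_counts Named integer vector of species per class.
#' @param baseline_log2_mean Named per-class mean log2 abundance.
#' @param species_log2_sd Between-species spread of baselines.
#' @param noise_log2_sd Replicate-level (biological) log2 noise.
#' @param tech_log2_sd Injection-level log2 noise.
#' @param batch_log2_shift Additive log2 shift per set.
#' @param effects Data frame `class_code`, `log2_fold`, `proportion`:
#'   each class's given proportion of species receives the log2 fold
#'   under hypoxia.
#' @param exclusive_counts Named vector: hypoxia-exclusive species per
#'   class.
#' @param exclusive_acyl Acyl required in every exclusive species.
#' @param dropout_midpoint,dropout_scale Logistic dropout in log2
#'   intensity: `P(missing) = plogis((midpoint - x) / scale)`. A midpoint
#'   of `-Inf` disables dropout.
#' @param n_blanks Number of blank runs.
#' @param contamination_rate Fraction of species contaminating blanks.
#' @param adduct_split_prob Probability a species is exported as two
#'   adduct rows.
#' @param n_junk_rows Low-quality rows (grade C or ppm out of tolerance)
#'   that the quality filter must remove.
#' @param n_sum_level Bulk (sum-composition) TG species in the inventory.
#' @param seed Integer seed; the seed fully determines the output.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_sets = 2L, n_reps = 9L, n_tech_reps = 2L,
                         class_counts = default_class_counts,
                         baseline_log2_mean = default_baselines,
                         species_log2_sd = 1.2,
                         noise_log2_sd = 0.5,
                         tech_log2_sd = 0.1,
                         batch_log2_shift = c(set1 = 0, set2 = 0.75),
                         effects = default_effects,
                         exclusive_counts = c(TG = 9L, PE = 2L),
                         exclusive_acyl = "16:4",
                         dropout_midpoint = 11,
                         dropout_scale = 1.5,
                         n_blanks = 3L,
                         contamination_rate = 0.06,
                         adduct_split_prob = 0.3,
                         n_junk_rows = 20L,
                         n_sum_level = 6L,
                         seed = 1L) {
  cfg <- list(n_sets = as.integer(n_sets), n_reps = as.integer(n_reps),
              n_tech_reps = as.integer(n_tech_reps),
              class_counts = class_counts,
              baseline_log2_mean = baseline_log2_mean,
              species_log2_sd = species_log2_sd,
              noise_log2_sd = noise_log2_sd, tech_log2_sd = tech_log2_sd,
              batch_log2_shift = batch_log2_shift,
              effects = effects,
              exclusive_counts = exclusive_counts,
              exclusive_acyl = exclusive_acyl,
              dropout_midpoint = dropout_midpoint,
              dropout_scale = dropout_scale,
              n_blanks = as.integer(n_blanks),
              contamination_rate = contamination_rate,
              adduct_split_prob = adduct_split_prob,
              n_junk_rows = as.integer(n_junk_rows),
              n_sum_level = as.integer(n_sum_level),
              seed = as.integer(seed))
  if (any(cfg$class_counts < 0) || any(cfg$n_reps < 1) ||
      cfg$n_sets < 1 || any(2^cfg$effects$log2_fold <= 0)) {
    condition_error("invalid generator configuration", "lipidflux_config_error")
  }
  if (length(cfg$batch_log2_shift) < cfg$n_sets) {
    cfg$batch_log2_shift <- stats::setNames(
      c(cfg$batch_log2_shift,
        rep(0, cfg$n_sets - length(cfg$batch_log2_shift))),
      paste0("set", seq_len(cfg$n_sets)))
  }
  structure(cfg, class = "synth_config")
}

# acyl pools by class family; constrained to plausible plant chains
acyl_pool <- function(class_code) {
  # 16:4 (and 16:3 for TG/DG) deliberately absent from the storage- and
  # phospholipid pools: in this system they mark the hypoxia-exclusive
  # species; galactolipids carry them constitutively
  switch(class_code,
    TG = , DG = c("14:0", "15:0", "16:0", "16:1", "16:2", "17:0",
                  "18:0", "18:1", "18:2", "18:3", "18:4", "20:0", "20:1",
                  "22:0", "24:0", "25:0", "26:0"),
    MGDG = , DGDG = c("16:0", "16:1", "16:2", "16:3", "16:4", "18:0",
                      "18:1", "18:2", "18:3"),
    PA = , PC = , PE = , PG = , PI = , PS = c("14:0", "15:0", "15:1",
                  "16:0", "16:1", "16:2", "17:0", "18:0", "18:1", "18:2",
                  "18:3", "18:4", "20:0", "20:1", "20:2", "22:0"),
    LPC = , LPE = c("14:0", "15:0", "15:1", "16:0", "16:1", "17:0", "17:1",
                    "18:0", "18:1", "18:2", "18:3", "19:0", "20:1", "20:2"),
    Cer = , HexCer = , SM = c("14:0", "16:0", "16:1", "18:0", "18:1",
                              "18:2", "20:0", "22:0", "22:1", "24:0",
                              "24:1", "26:0", "26:1"),
    SE = , AHexSit = c("14:0", "15:0", "16:0", "16:1", "17:0", "18:0",
                       "18:1", "18:2", "18:3", "20:0", "20:1", "20:4",
                       "22:0", "22:1", "24:0", "26:0"),
    PR = c("10:2", "15:3", "20:4", "20:5", "25:5", "30:6", "35:7", "40:8",
           "45:9", "50:10"),
    c("16:0", "18:1", "18:2")
  )
}

# species the study names explicitly; kept verbatim in every inventory
named_species <- c(
  "TG 54:7", "TG 54:8", "TG 52:5", "TG 52:6", "TG 53:5",
  "PC 18:1_18:2", "PC 16:0_18:1", "MGDG 18:2_18:2",
  "LPC 17:0", "LPC 18:2", "DG 24:0_18:3", "DG 26:0_18:3"
)

named_exclusives <- c("TG 16:3_16:4_18:2", "PE 16:4_18:2", "PE 16:4_18:3")

build_inventory <- function(cfg, vocabulary) {
  rng_names <- function(class_code, n, forced_acyl = NULL) {
    k <- vocabulary$n_chains[match(class_code, vocabulary$class_code)]
    pool <- acyl_pool(class_code)
    out <- character(0)
    guard <- 0L
    while (length(out) < n && guard < 200L) {
      guard <- guard + 1L
      m <- max(n * 2L, 10L)
      chains <- replicate(m, {
        ch <- sample(pool, k, replace = TRUE)
        if (!is.null(forced_acyl)) ch[1L] <- forced_acyl
        paste(ch, collapse = "_")
      })
      nm <- canonical_names(paste(class_code, chains), vocabulary)
      out <- unique(c(out, nm))
    }
    if (length(out) < n) {
      condition_error(sprintf("cannot draw %d distinct %s species", n,
                              class_code), "lipidflux_config_error")
    }
    out[seq_len(n)]
  }

  inventory <- character(0)
  for (cl in names(cfg$class_counts)) {
    n <- cfg$class_counts[[cl]]
    if (n == 0L) next
    fixed <- named_species[startsWith(named_species, paste0(cl, " "))]
    fixed <- fixed[seq_len(min(length(fixed), n))]
    need <- n - length(fixed)
    extra <- if (need > 0L) {
      cand <- setdiff(rng_names(cl, need + length(fixed)), fixed)
      if (length(cand) < need) {
        condition_error(sprintf("cannot draw %d distinct %s species",
                                n, cl), "lipidflux_config_error")
      }
      cand[seq_len(need)]
    } else character(0)
    inventory <- c(inventory, fixed, extra)
  }
  inventory <- unique(inventory)

  exclusives <- character(0)
  for (cl in names(cfg$exclusive_counts)) {
    n <- cfg$exclusive_counts[[cl]]
    fixed <- named_exclusives[startsWith(named_exclusives, paste0(cl, " "))]
    fixed <- fixed[seq_len(min(length(fixed), n))]
    need <- n - length(fixed)
    extra <- if (need > 0L) {
      cand <- rng_names(cl, need + 10L, forced_acyl = cfg$exclusive_acyl)
      setdiff(cand, c(inventory, fixed))[seq_len(need)]
    } else character(0)
    exclusives <- c(exclusives, fixed, extra)
  }
  exclusives <- canonical_names(exclusives, vocabulary)
  inventory <- setdiff(inventory, exclusives)
  # internal-standard compositions are reserved names
  inventory <- setdiff(inventory, canonical_names(standard_compositions,
                                                  vocabulary))
  list(base = inventory, exclusive = exclusives)
}

standard_compositions <- c(
  TG = "TG 17:1_17:1_17:1", DG = "DG 17:1_17:1", MGDG = "MGDG 17:1_17:1",
  DGDG = "DGDG 17:1_17:1", PA = "PA 17:1_17:1", PC = "PC 15:1_15:1",
  PE = "PE 15:1_15:1", PG = "PG 15:1_15:1", PI = "PI 15:1_15:1",
  LPC = "LPC 18:1", LPE = "LPE 18:1", Cer = "Cer 18:1_15:0",
  HexCer = "HexCer 18:1_15:0", SM = "SM 18:1_15:0", SE = "SE 22:1",
  AHexSit = "AHexSit 22:1", PR = "PR 20:5"
)

#' Generate a synthetic lipidomics experiment
#'
#' Draws log2 intensities as
#' `baseline(species) + condition effect + batch shift + noise`,
#' exponentiates to peak areas, applies logistic intensity-dependent
#' dropout, splits a configurable fraction of species into two adduct
#' rows whose areas sum to the species total, emits technical replicate
#' injections, spikes one internal standard per class at constant level
#' with small multiplicative noise, contaminates blanks for a configured
#' subset of species (half of them violating the 5-fold rule, half not),
#' and emits hypoxia-exclusive species only under hypoxia. The seed fully
#' determines the output.
#'
#' @param config A [synth_config()].
#' @return A list: `records` (raw export data frame: `name`, `adduct`,
#'   `grade`, `ppm`, one area column per injection), `blank_records`
#'   (same layout, blank runs), `standard_map` (class_code,
#'   standard_name, amount), `samples` (biological-sample metadata),
#'   `truth` (a `GroundTruth` list: per-species effects, exclusivity
#'   labels, blank contamination folds, per-class planted enrichment).
#' @export
generate_lipidomics <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  set.seed(cfg$seed)
  vocabulary <- lipid_vocabulary()

  inv <- build_inventory(cfg, vocabulary)
  species <- c(inv$base, inv$exclusive)
  sp_tab <- species_table(species, vocabulary)
  n_sp <- nrow(sp_tab)
  is_exclusive <- sp_tab$name %in% inv$exclusive

  # sample metadata
  sets <- paste0("set", seq_len(cfg$n_sets))
  samples <- expand.grid(replicate = seq_len(cfg$n_reps),
                         condition = c("control", "hypoxia"),
                         set_id = sets, stringsAsFactors = FALSE)
  samples$sample_id <- sprintf("%s_%s_r%d", samples$set_id,
                               substr(samples$condition, 1L, 4L),
                               samples$replicate)
  samples$is_blank <- FALSE
  samples <- samples[, c("sample_id", "condition", "set_id", "replicate",
                         "is_blank")]

  # per-species baseline and planted condition effect
  class_mu <- cfg$baseline_log2_mean[sp_tab$class_code]
  class_mu[is.na(class_mu)] <- mean(cfg$baseline_log2_mean)
  baseline <- class_mu + stats::rnorm(n_sp, 0, cfg$species_log2_sd)
  true_lfc <- numeric(n_sp)
  for (i in seq_len(nrow(cfg$effects))) {
    eff <- cfg$effects[i, ]
    members <- which(sp_tab$class_code == eff$class_code & !is_exclusive)
    n_hit <- round(eff$proportion * length(members))
    hit <- sample(members, n_hit)
    true_lfc[hit] <- eff$log2_fold
  }
  # exclusives appear at moderate abundance under hypoxia only
  baseline[is_exclusive] <- class_mu[is_exclusive] - 1

  # biological log2 intensity matrix
  n_samples <- nrow(samples)
  shift <- cfg$batch_log2_shift[samples$set_id]
  effect <- outer(true_lfc, as.integer(samples$condition == "hypoxia"))
  logx <- baseline + effect + matrix(rep(shift, each = n_sp), n_sp) +
    matrix(stats::rnorm(n_sp * n_samples, 0, cfg$noise_log2_sd), n_sp)
  rownames(logx) <- sp_tab$name
  colnames(logx) <- samples$sample_id

  # exclusivity: never present under control
  logx[is_exclusive, samples$condition == "control"] <- NA_real_

  # intensity-dependent dropout
  p_miss <- stats::plogis((cfg$dropout_midpoint - logx) / cfg$dropout_scale)
  drop <- matrix(stats::runif(n_sp * n_samples), n_sp) < p_miss
  logx[drop] <- NA_real_

  # raw export rows: adduct split, technical replicates (vectorized)
  split_species <- stats::runif(n_sp) < cfg$adduct_split_prob
  adduct_w <- stats::runif(n_sp, 0.55, 0.85)
  inj_names <- as.vector(outer(samples$sample_id,
                               paste0(".t", seq_len(cfg$n_tech_reps)),
                               paste0))
  areas <- 2^logx
  grade_sp <- sample(c("A", "B"), n_sp, replace = TRUE, prob = c(0.7, 0.3))

  row_sp <- c(seq_len(n_sp), which(split_species))
  row_w <- c(ifelse(split_species, adduct_w, 1), 1 - adduct_w[split_species])
  row_adduct <- c(rep("+H", n_sp), rep("+Na", sum(split_species)))
  row_name <- sp_tab$name[row_sp]
  row_grade <- grade_sp[row_sp]
  row_ppm <- stats::runif(length(row_sp), -4.5, 4.5)
  row_area <- areas[row_sp, , drop = FALSE] * row_w

  # internal standards: constant spike, no dropout, never split
  std_classes <- intersect(names(cfg$class_counts)[cfg$class_counts > 0],
                           names(standard_compositions))
  standard_map <- data.frame(class_code = std_classes,
                             standard_name = standard_compositions[std_classes],
                             amount = 100, row.names = NULL,
                             stringsAsFactors = FALSE)
  std_area <- matrix(2^(17 + stats::rnorm(length(std_classes) * n_samples,
                                          0, 0.07)),
                     nrow = length(std_classes))
  row_name <- c(row_name, unname(standard_compositions[std_classes]))
  row_adduct <- c(row_adduct, rep("+H", length(std_classes)))
  row_grade <- c(row_grade, rep("A", length(std_classes)))
  row_ppm <- c(row_ppm, stats::runif(length(std_classes), -2, 2))
  row_area <- rbind(row_area, std_area)

  # junk rows the quality filter must remove
  if (cfg$n_junk_rows > 0L) {
    j <- seq_len(cfg$n_junk_rows)
    bad_grade <- j %% 2L == 0L
    row_name <- c(row_name, sample(sp_tab$name, cfg$n_junk_rows,
                                   replace = TRUE))
    row_adduct <- c(row_adduct, rep("+NH4", cfg$n_junk_rows))
    row_grade <- c(row_grade, ifelse(bad_grade, "C", "A"))
    row_ppm <- c(row_ppm, ifelse(bad_grade, stats::runif(cfg$n_junk_rows,
                                                         -4.5, 4.5),
                                 stats::runif(cfg$n_junk_rows, 6, 12)))
    row_area <- rbind(row_area,
                      matrix(2^stats::rnorm(cfg$n_junk_rows * n_samples,
                                            12, 1),
                             nrow = cfg$n_junk_rows))
  }

  n_rows <- length(row_name)
  inj <- matrix(NA_real_, nrow = n_rows, ncol = length(inj_names),
                dimnames = list(NULL, inj_names))
  for (t in seq_len(cfg$n_tech_reps)) {
    cols <- (t - 1L) * n_samples + seq_len(n_samples)
    inj[, cols] <- row_area *
      2^matrix(stats::rnorm(n_rows * n_samples, 0, cfg$tech_log2_sd), n_rows)
  }
  records <- cbind(
    data.frame(name = row_name, adduct = row_adduct, grade = row_grade,
               ppm = row_ppm, stringsAsFactors = FALSE),
    as.data.frame(inj, check.names = FALSE))

  # blanks: contamination for a subset; half planted below the 5-fold rule
  blank_ids <- paste0("blank_", seq_len(cfg$n_blanks))
  n_cont <- round(cfg$contamination_rate * n_sp)
  cont <- sample(which(!is_exclusive), n_cont)
  sample_mean <- rowMeans(areas, na.rm = TRUE)
  blank_fold <- rep(NA_real_, n_sp)
  # first half: fold 1.5-4 (excluded); second half: fold 8-30 (retained)
  n_bad <- ceiling(n_cont / 2)
  blank_fold[cont[seq_len(n_bad)]] <- stats::runif(n_bad, 1.5, 4)
  blank_fold[cont[-seq_len(n_bad)]] <- stats::runif(n_cont - n_bad, 8, 30)
  blank_rows <- lapply(cont, function(i) {
    level <- sample_mean[i] / blank_fold[i]
    v <- level * 2^stats::rnorm(cfg$n_blanks, 0, 0.2)
    df <- data.frame(name = sp_tab$name[i], adduct = "+H", grade = "A",
                     ppm = stats::runif(1L, -4.5, 4.5),
                     stringsAsFactors = FALSE)
    cbind(df, stats::setNames(as.data.frame(as.list(v)), blank_ids))
  })
  blank_records <- if (length(blank_rows)) do.call(rbind, blank_rows) else
    cbind(data.frame(name = character(0), adduct = character(0),
                     grade = character(0), ppm = numeric(0)),
          stats::setNames(as.data.frame(matrix(numeric(0), 0, cfg$n_blanks)),
                          blank_ids))

  planted_classes <- cfg$effects$class_code[cfg$effects$log2_fold != 0]
  truth <- structure(list(
    species = data.frame(
      name = sp_tab$name, class_code = sp_tab$class_code,
      category = sp_tab$category,
      baseline_log2 = baseline, true_log2fc = true_lfc,
      exclusive_condition = ifelse(is_exclusive, "hypoxia", NA_character_),
      blank_contaminated = seq_len(n_sp) %in% cont,
      blank_fold = blank_fold,
      stringsAsFactors = FALSE),
    batch_log2_shift = cfg$batch_log2_shift,
    planted_classes = planted_classes,
    effects = cfg$effects,
    config = cfg), class = "ground_truth")

  list(records = records, blank_records = blank_records,
       standard_map = standard_map, samples = samples, truth = truth)
}

#' Audit pipeline results against the generator's ground truth
#'
#' @param results A list with any of: `exclusive` (output of
#'   [exclusive_species()]), `differential` (output of [multi_ttest()]),
#'   `enrichment` (output of [class_enrichment()]), and `universe`
#'   (character vector of analyzed species names; required).
#' @param truth The `ground_truth` emitted by [generate_lipidomics()].
#' @return A list: `exclusive` (sensitivity/recall, precision, counts),
#'   `fold_sign_accuracy` (share of truly perturbed species whose
#'   estimated fold has the planted sign), `enrichment_hits` (per planted
#'   class: whether it was called in the planted direction).
#' @export
truth_audit <- function(results, truth) {
  stopifnot(inherits(truth, "ground_truth"), !is.null(results$universe))
  known <- c(truth$species$name,
             canonical_names(standard_compositions))
  if (!all(results$universe %in% known)) {
    condition_error("results universe contains species unknown to the ground truth",
                    "lipidflux_data_error")
  }
  ts <- truth$species[truth$species$name %in% results$universe, , drop = FALSE]
  out <- list()
  if (!is.null(results$exclusive)) {
    called <- results$exclusive$hypoxia
    actual <- ts$name[!is.na(ts$exclusive_condition)]
    tp <- length(intersect(called, actual))
    out$exclusive <- list(
      recall = if (length(actual)) tp / length(actual) else NA_real_,
      precision = if (length(called)) tp / length(called) else NA_real_,
      n_called = length(called), n_true = length(actual))
  }
  if (!is.null(results$differential)) {
    d <- results$differential
    idx <- match(ts$name[ts$true_log2fc != 0], d$unit)
    est <- d$log2_fold_change[idx[!is.na(idx)]]
    tru <- ts$true_log2fc[ts$true_log2fc != 0][!is.na(idx)]
    out$fold_sign_accuracy <- if (length(est)) mean(sign(est) == sign(tru))
                              else NA_real_
  }
  if (!is.null(results$enrichment)) {
    e <- results$enrichment
    hits <- vapply(seq_len(nrow(truth$effects)), function(i) {
      cl <- truth$effects$class_code[i]
      want <- if (truth$effects$log2_fold[i] > 0) "enriched" else "depleted"
      row <- e[e$class_code == cl, , drop = FALSE]
      nrow(row) == 1L && row$direction == want
    }, logical(1L))
    out$enrichment_hits <- stats::setNames(hits, truth$effects$class_code)
  }
  out
}
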