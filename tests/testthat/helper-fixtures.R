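# Fixture builders shared across test files; everything is generated in
# code, nothing is read from disk.

bio_samples <- function(n_reps = 2L, sets = c("set1", "set2")) {
  g <- expand.grid(replicate = seq_len(n_reps),
                   condition = c("control", "hypoxia"),
                   set_id = sets, stringsAsFactors = FALSE)
  g$sample_id <- sprintf("%s_%s_r%d", g$set_id, substr(g$condition, 1, 4),
                         g$replicate)
  g$is_blank <- FALSE
  g[, c("sample_id", "condition", "set_id", "replicate", "is_blank")]
}

# lipid_table from a species-named matrix
make_table <- function(values, samples, stage = "merged") {
  lipid_table(values, species_table(rownames(values)), samples, stage = stage)
}

# deterministic supply of valid, distinct TG molecular-species names
tg_names <- local({
  pool <- c("14:0", "15:0", "16:0", "16:1", "17:0", "18:0", "18:1", "18:2",
            "18:3", "20:0", "20:1", "22:0", "24:0", "26:0")
  combos <- expand.grid(a = pool, b = pool, c = pool,
                        stringsAsFactors = FALSE)
  nms <- unique(canonical_names(paste0("TG ", combos$a, "_", combos$b, "_",
                                       combos$c)))
  function(n) {
    stopifnot(n <= length(nms))
    nms[seq_len(n)]
  }
})

# random positive intensity table on the generator's log-normal scale
random_table <- function(n_species = 30L, n_reps = 3L, seed = 1L,
                         missing_frac = 0.1) {
  set.seed(seed)
  samples <- bio_samples(n_reps)
  v <- matrix(2^rnorm(n_species * nrow(samples), 16, 1.5), n_species,
              dimnames = list(tg_names(n_species), samples$sample_id))
  if (missing_frac > 0) {
    v[sample(length(v), round(missing_frac * length(v)))] <- NA_real_
  }
  make_table(v, samples)
}

# hand-built 12-species toy: exercises the 5-fold blank rule, the 50%
# presence rule and the both-sets rule; survivors enumerated below
toy_fixture <- function() {
  samples <- bio_samples(n_reps = 2L)
  ids <- samples$sample_id
  s1 <- samples$set_id == "set1"
  ctl <- samples$condition == "control"
  hyp <- samples$condition == "hypoxia"

  nm <- c("PC 16:0_18:1",       # 1 clean, everywhere -> survives
          "PC 16:0_18:2",       # 2 blank ratio 10 -> survives
          "TG 16:0_18:1_18:2",  # 3 blank ratio 4  -> blank rule removes
          "TG 16:0_18:2_18:2",  # 4 blank ratio exactly 5 -> survives
          "PE 16:0_18:2",       # 5 set1 only -> both-sets rule removes
          "PE 16:0_18:3",       # 6 50% of control, both sets -> survives
          "PA 16:0_18:1",       # 7 25% per condition -> presence removes
          "DG 16:0_18:1",       # 8 clean, everywhere -> survives
          "LPC 18:2",           # 9 hypoxia-exclusive, 100% -> survives
          "MGDG 18:2_18:3",     # 10 blank ratio 100 -> survives
          "TG 18:1_18:1_18:1",  # 11 set2 only -> both-sets rule removes
          "DGDG 18:2_18:3")     # 12 detected once -> presence removes
  v <- matrix(NA_real_, 12L, length(ids), dimnames = list(nm, ids))
  v[1, ] <- 100
  v[2, ] <- 100
  v[3, ] <- 100
  v[4, ] <- 100
  v[5, s1] <- 100
  v[6, c("set1_cont_r1", "set2_cont_r1")] <- 100
  v[7, c("set1_cont_r1", "set2_hypo_r1")] <- 100
  v[8, ] <- 50
  v[9, hyp] <- 200
  v[10, ] <- 1000
  v[11, !s1] <- 100
  v[12, "set1_cont_r1"] <- 100

  blank_ids <- c("blank_1", "blank_2")
  bv <- matrix(NA_real_, 12L, 2L, dimnames = list(nm, blank_ids))
  bv[2, ] <- 10
  bv[3, ] <- 25
  bv[4, ] <- 20
  bv[10, ] <- 10
  blank_samples <- data.frame(sample_id = blank_ids, condition = "blank",
                              set_id = "blank", replicate = 1:2,
                              is_blank = TRUE, stringsAsFactors = FALSE)
  keep <- which(rowSums(!is.na(bv)) > 0L)
  blanks <- lipid_table(bv[keep, , drop = FALSE],
                        species_table(nm[keep]), blank_samples,
                        stage = "merged")
  list(table = make_table(v, samples),
       blanks = blanks,
       survivors = sort(canonical_names(nm[c(1, 2, 4, 6, 8, 9, 10)])))
}

# compact generator configuration for fast simulation loops
small_config <- function(seed = 1L, ...) {
  args <- list(
    class_counts = c(TG = 30, PC = 15, PE = 10, DG = 8, LPC = 6, MGDG = 6),
    exclusive_counts = c(TG = 3L),
    n_junk_rows = 6L,
    seed = seed
  )
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(synth_config, args)
}
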