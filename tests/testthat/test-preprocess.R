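area_cols <- function(records) {
  setdiff(names(records), c("name", "adduct", "grade", "ppm"))
}

test_that("quality filter keeps only accepted grades within ppm tolerance", {
  rec <- data.frame(name = rep("PC 34:2", 4),
                    adduct = c("+H", "+Na", "+H", "+H"),
                    grade = c("A", "B", "C", "A"),
                    ppm = c(3, -4.9, 1, 6),
                    s1 = 1:4, stringsAsFactors = FALSE)
  out <- quality_filter(rec, grades = c("A", "B"), max_ppm = 5)
  expect_equal(out$grade, c("A", "B"))
  expect_equal(quality_filter(rec[0, ], c("A", "B")), rec[0, ])
})

test_that("adduct merging sums per sample with missing-aware semantics", {
  samples <- bio_samples(n_reps = 1L, sets = "set1")  # 2 samples
  rec <- data.frame(name = c("PC 34:2", "PC 34:2", "DG 16:0_18:1"),
                    adduct = c("+H", "+Na", "+H"),
                    grade = "A", ppm = 0, stringsAsFactors = FALSE)
  rec[[samples$sample_id[1]]] <- c(100, 50, 7)
  rec[[samples$sample_id[2]]] <- c(200, NA, 9)
  tab <- merge_adducts(rec, samples)
  expect_equal(unname(tab$values["PC 34:2", ]), c(150, 200))
  # single-adduct rows pass through unchanged
  expect_equal(unname(tab$values["DG 16:0_18:1", ]), c(7, 9))
  # conservation of total non-missing area
  expect_equal(sum(tab$values, na.rm = TRUE),
               sum(as.matrix(rec[samples$sample_id]), na.rm = TRUE))
})

test_that("chain-order variants of one species merge and missing+missing stays missing", {
  samples <- bio_samples(n_reps = 1L, sets = "set1")
  rec <- data.frame(name = c("TG 18:2_16:0_18:3", "TG 16:0_18:3_18:2"),
                    adduct = c("+H", "+Na"), grade = "A", ppm = 0,
                    stringsAsFactors = FALSE)
  rec[[samples$sample_id[1]]] <- c(10, 20)
  rec[[samples$sample_id[2]]] <- c(NA, NA)
  tab <- merge_adducts(rec, samples)
  expect_equal(nrow(tab$values), 1L)
  expect_equal(rownames(tab$values), "TG 16:0_18:2_18:3")
  expect_equal(unname(tab$values[1, ]), c(30, NA))
})

test_that("unparseable names in a record table are reported as a parse error", {
  samples <- bio_samples(n_reps = 1L, sets = "set1")
  rec <- data.frame(name = c("PC 34:2", "XX 18:1"), adduct = "+H",
                    grade = "A", ppm = 0, stringsAsFactors = FALSE)
  rec[[samples$sample_id[1]]] <- c(1, 2)
  rec[[samples$sample_id[2]]] <- c(1, 2)
  expect_error(merge_adducts(rec, samples), class = "lipidflux_parse_error")
})

test_that("zero areas are treated as non-detections", {
  samples <- bio_samples(n_reps = 1L)
  v <- matrix(c(0, 5, 3, 0, 2, 8, 0, 0), 2,
              dimnames = list(tg_names(2), samples$sample_id))
  tab <- make_table(v, samples)
  expect_true(is.na(tab$values[1, 1]))
  expect_equal(sum(is.na(tab$values)), 4L)
})

test_that("technical replicate injections average into one column per sample", {
  rec <- data.frame(name = "PC 34:2", adduct = "+H", grade = "A", ppm = 0,
                    stringsAsFactors = FALSE)
  rec[["a.t1"]] <- 10; rec[["a.t2"]] <- 14
  rec[["b.t1"]] <- NA_real_; rec[["b.t2"]] <- 8
  rec[["c.t1"]] <- NA_real_; rec[["c.t2"]] <- NA_real_
  out <- average_technical_replicates(rec)
  expect_equal(out$a, 12)
  expect_equal(out$b, 8)    # mean over non-missing injections
  expect_true(is.na(out$c))
  expect_equal(area_cols(out), c("a", "b", "c"))
})

test_that("blank exclusion follows the 5-fold rule with an inclusive boundary", {
  fx <- toy_fixture()
  out <- blank_filter(fx$table, fx$blanks, min_fold = 5)
  expect_false("TG 16:0_18:1_18:2" %in% rownames(out$values))  # ratio 4
  expect_true("TG 16:0_18:2_18:2" %in% rownames(out$values))   # ratio 5
  expect_true("PC 16:0_18:2" %in% rownames(out$values))        # ratio 10
  expect_true("PC 16:0_18:1" %in% rownames(out$values))        # absent in blanks
  # removed species logged with their ratio
  expect_equal(out$log$species[out$log$rule == "blank_filter"],
               "TG 16:0_18:1_18:2")
  expect_equal(out$log$statistic[out$log$rule == "blank_filter"], 4)
  # surviving values never altered by a filter
  expect_equal(out$values["PC 16:0_18:1", ],
               fx$table$values["PC 16:0_18:1", ])
})

test_that("internal-standard normalization divides classwise and drops standards", {
  samples <- bio_samples(n_reps = 1L, sets = "set1")
  nm <- c("PC 34:2", "PC 36:4", "PC 15:1_15:1", "DG 16:0_18:1", "DG 17:1_17:1")
  v <- matrix(c(300, 90, 150, 60, 30,
                600, 180, 300, 120, 60), 5,
              dimnames = list(nm, samples$sample_id))
  tab <- make_table(v, samples)
  smap <- data.frame(class_code = c("PC", "DG"),
                     standard_name = c("PC 15:1_15:1", "DG 17:1_17:1"),
                     stringsAsFactors = FALSE)
  out <- internal_standard_normalize(tab, smap)
  expect_equal(unname(out$values["PC 34:2", ]), c(2, 2))
  expect_equal(unname(out$values["DG 16:0_18:1", ]), c(2, 2))
  expect_false(any(smap$standard_name %in% rownames(out$values)))
  # proportional standard drift across samples cancels exactly
  expect_equal(out$values[, 1], out$values[, 2])
})

test_that("standard normalization errors are specific", {
  samples <- bio_samples(n_reps = 1L, sets = "set1")
  nm <- c("PC 34:2", "PC 15:1_15:1")
  v <- matrix(c(300, 150, 600, NA), 2, dimnames = list(nm, samples$sample_id))
  tab <- make_table(v, samples)
  smap <- data.frame(class_code = "PC", standard_name = "PC 15:1_15:1",
                     stringsAsFactors = FALSE)
  expect_error(internal_standard_normalize(tab, smap),
               class = "lipidflux_data_error")  # standard missing in a sample
  v2 <- matrix(c(300, 150, 600, 300), 2, dimnames = list(nm, samples$sample_id))
  expect_error(internal_standard_normalize(
    make_table(v2, samples),
    data.frame(class_code = "DG", standard_name = "DG 17:1_17:1")),
    class = "lipidflux_config_error")  # PC unmapped
})

test_that("median normalization equalizes per-sample medians at the reference", {
  samples <- bio_samples(n_reps = 1L, sets = "set1")
  v <- matrix(c(1, 2, 3, 4, 8, 16), 3,
              dimnames = list(tg_names(3), samples$sample_id))
  tab <- make_table(v, samples)
  out <- median_normalize(tab)
  # medians 2 and 8 -> reference 5 -> factors 2.5 and 0.625
  expect_equal(unname(out$values[, 1]), c(2.5, 5, 7.5))
  expect_equal(unname(out$values[, 2]), c(2.5, 5, 10))
  meds <- apply(out$values, 2, median, na.rm = TRUE)
  expect_lt(diff(range(meds)), 1e-12)
})

test_that("median normalization is idempotent and errors on an all-missing sample", {
  tab <- random_table(seed = 11)
  once <- median_normalize(tab)
  again <- median_normalize(make_table(once$values, once$samples))
  expect_equal(again$values, once$values, tolerance = 1e-12)
  bad <- tab
  bad$values[, 1] <- NA_real_
  expect_error(median_normalize(bad), class = "lipidflux_data_error")
})

test_that("per-sample medians agree after normalization on random tables", {
  for (seed in 1:10) {
    out <- median_normalize(random_table(seed = seed, missing_frac = 0.2))
    meds <- apply(out$values, 2, median, na.rm = TRUE)
    expect_lt(diff(range(meds)), 1e-9)
  }
})

test_that("presence filter enforces the within-condition and both-sets rules", {
  samples <- bio_samples(n_reps = 9L)  # 9+9 per set
  ctl <- which(samples$condition == "control")
  hyp <- which(samples$condition == "hypoxia")
  set1 <- which(samples$set_id == "set1")
  nm <- tg_names(3)
  v <- matrix(NA_real_, 3, nrow(samples),
              dimnames = list(nm, samples$sample_id))
  v[1, hyp] <- 10                                   # 18/18 hypoxia
  v[1, intersect(ctl, which(samples$replicate <= 2))] <- 10  # 4/18 control
  v[2, c(ctl[1:4], hyp[1:4])] <- 10                 # 4/9 per condition in set1
  v[2, setdiff(seq_len(nrow(samples)), set1)[1]] <- 10  # one set2 detection
  v[3, intersect(set1, hyp)] <- 10                  # 9/9 hypoxia, set1 only
  tab <- make_table(v, samples)
  out <- presence_filter(tab, min_frac = 0.5, require_both_sets = TRUE)
  expect_equal(rownames(out$values), nm[1])
  # without the both-sets requirement the set1-only species passes
  out2 <- presence_filter(make_table(v, samples), require_both_sets = FALSE)
  expect_true(nm[3] %in% rownames(out2$values))
})

test_that("stages advance only forward along the pipeline order", {
  fx <- toy_fixture()
  filtered <- presence_filter(fx$table)
  expect_error(blank_filter(filtered, fx$blanks),
               class = "lipidflux_stage_error")
  expect_error(median_normalize(filtered), class = "lipidflux_stage_error")
})

test_that("the toy table loses exactly the rule-violating species", {
  fx <- toy_fixture()
  out <- presence_filter(blank_filter(fx$table, fx$blanks, min_fold = 5))
  expect_equal(sort(rownames(out$values)), fx$survivors)
})
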