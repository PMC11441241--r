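# table with a planted per-set log2 batch shift and optional condition fold
batch_sim_table <- function(n_species = 100L, n_reps = 9L, delta = 2,
                            lfc = 0, noise_sd = 0.5, seed = 1L) {
  set.seed(seed)
  samples <- bio_samples(n_reps = n_reps)
  baseline <- rnorm(n_species, 16, 1)
  logx <- matrix(baseline, n_species, nrow(samples),
                 dimnames = list(tg_names(n_species), samples$sample_id)) +
    matrix(rnorm(n_species * nrow(samples), 0, noise_sd), n_species)
  logx[, samples$set_id == "set2"] <- logx[, samples$set_id == "set2"] + delta
  logx[, samples$condition == "hypoxia"] <-
    logx[, samples$condition == "hypoxia"] + lfc
  make_table(2^logx, samples)
}

test_that("the PCA presence filter uses an inclusive fraction over all samples", {
  samples <- bio_samples(n_reps = 9L)  # 36 samples; use first 18 detections
  nm <- tg_names(3)
  v <- matrix(NA_real_, 3, 36, dimnames = list(nm, samples$sample_id))
  v[1, 1:20] <- 1   # 20/36 = 55.6%
  v[2, 1:18] <- 1   # exactly 50%
  v[3, 1:17] <- 1   # 47.2%
  out <- pca_presence_filter(make_table(v, samples), min_frac = 0.5)
  expect_equal(rownames(out$values), nm[1:2])
})

test_that("missing-value completion fills flagged values and keeps observed ones", {
  tab <- random_table(seed = 3, missing_frac = 0.2)
  out <- complete_missing(tab, "half_min")
  expect_false(anyNA(out$values))
  was_na <- is.na(tab$values)
  expect_equal(out$values[!was_na], tab$values[!was_na])
  i <- which(rowSums(was_na) > 0)[1]
  expect_equal(unique(out$values[i, was_na[i, ]]),
               min(tab$values[i, ], na.rm = TRUE) / 2)
  expect_true(any(out$log$action == "completed"))
  z <- complete_missing(tab, "zero")
  expect_true(all(z$values[was_na] == 0))
})

test_that("zero completion and row-median completion behave as documented", {
  tab <- random_table(seed = 4, missing_frac = 0.2)
  was_na <- is.na(tab$values)
  rm <- complete_missing(tab, "row_median")
  i <- which(rowSums(was_na) > 0)[1]
  expect_equal(unique(rm$values[i, was_na[i, ]]),
               median(tab$values[i, ], na.rm = TRUE))
})

test_that("a single batch passes through batch adjustment unchanged", {
  tab <- random_table(seed = 5, missing_frac = 0)
  tab$samples$set_id <- "set1"
  res <- batch_adjust(tab)
  expect_equal(res$table$values, tab$values)
  expect_null(res$model)
  expect_equal(res$table$stage, "batch_adjusted")
})

test_that("batch adjustment matches the sva reference implementation", {
  skip_if_not_installed("sva")
  tab <- batch_sim_table(n_species = 60L, n_reps = 6L, delta = 1.5,
                         lfc = 0.8, seed = 42)
  res <- batch_adjust(tab)
  dat <- log2(tab$values)
  mod <- model.matrix(~condition, data = tab$samples)
  ref <- suppressMessages(
    sva::ComBat(dat = dat, batch = tab$samples$set_id, mod = mod,
                par.prior = TRUE))
  expect_equal(log2(res$table$values), ref, tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("a planted additive batch shift is removed (near-noise-free limit)", {
  tab <- batch_sim_table(n_species = 80L, delta = 2, noise_sd = 1e-6, seed = 6)
  res <- batch_adjust(tab)
  lx <- log2(res$table$values)
  s2 <- tab$samples$set_id == "set2"
  resid <- rowMeans(lx[, s2]) - rowMeans(lx[, !s2])
  expect_lt(max(abs(resid)), 1e-6)
  # dimensions and species never change
  expect_equal(dim(res$table$values), dim(tab$values))
  expect_equal(rownames(res$table$values), rownames(tab$values))
})

test_that("the condition effect survives adjustment of a confounding batch shift", {
  est <- vapply(1:20, function(seed) {
    tab <- batch_sim_table(n_species = 60L, delta = 2, lfc = 1, seed = seed)
    res <- batch_adjust(tab)
    lx <- log2(res$table$values)
    hyp <- tab$samples$condition == "hypoxia"
    mean(rowMeans(lx[, hyp]) - rowMeans(lx[, !hyp]))
  }, numeric(1))
  expect_lt(abs(mean(est) - 1), 0.1)
})

test_that("zero-variance species are flagged and left unadjusted", {
  tab <- batch_sim_table(n_species = 20L, delta = 1, seed = 7)
  tab$values[1, ] <- 1000
  res <- batch_adjust(tab)
  expect_equal(res$model$zero_variance_species, rownames(tab$values)[1])
  expect_equal(unname(res$table$values[1, ]), rep(1000, ncol(tab$values)))
})

test_that("batch adjustment commutes with species reordering", {
  tab <- batch_sim_table(n_species = 30L, delta = 1.2, seed = 8)
  res1 <- batch_adjust(tab)
  perm <- sample(nrow(tab$values))
  tab2 <- tab
  tab2$values <- tab$values[perm, ]
  tab2$species <- tab$species[perm, ]
  res2 <- batch_adjust(tab2)
  expect_equal(res2$table$values, res1$table$values[perm, ], tolerance = 1e-8)
})

test_that("PCA reports unit-norm loadings, normalized contributions and rank-1 structure", {
  samples <- bio_samples(n_reps = 3L)
  n <- nrow(samples)
  base <- 2^seq(10, 12, length.out = n)
  v <- outer(c(1, 2, 4, 8), base)  # exact rank-1 in log2? no: rank-1 in linear
  rownames(v) <- tg_names(4)
  colnames(v) <- samples$sample_id
  tab <- make_table(v, samples)
  pca <- run_pca(tab, dims = 2, scale. = FALSE)
  # log2 of a rank-1 positive matrix is additive -> single PC carries all variance
  expect_equal(pca$explained_frac[1], 1, tolerance = 1e-10)
  expect_equal(colSums(pca$contributions), c(PC1 = 1, PC2 = 1), tolerance = 1e-9)
  expect_equal(unname(colSums(pca$loadings^2)), c(1, 1), tolerance = 1e-9)
})

test_that("all components reconstruct the centered matrix", {
  tab <- random_table(seed = 9, missing_frac = 0)
  pca <- run_pca(tab, dims = 2)
  recon <- pca$scores_all %*% t(pca$loadings_all)
  expect_lt(max(abs(recon - pca$centered)), 1e-8)
})

test_that("sample permutation permutes scores and preserves explained variance", {
  tab <- random_table(seed = 10, missing_frac = 0)
  pca1 <- run_pca(tab, dims = 3)
  perm <- sample(ncol(tab$values))
  tab2 <- tab
  tab2$values <- tab$values[, perm]
  tab2$samples <- tab$samples[perm, ]
  pca2 <- run_pca(tab2, dims = 3)
  expect_equal(pca2$explained_frac, pca1$explained_frac, tolerance = 1e-10)
  for (d in 1:3) {  # scores match up to the SVD sign ambiguity
    s1 <- pca1$scores[perm, d]
    s2 <- pca2$scores[, d]
    expect_true(isTRUE(all.equal(s1, s2, tolerance = 1e-8)) ||
                isTRUE(all.equal(s1, -s2, tolerance = 1e-8)))
  }
})

test_that("requesting more dimensions than the rank errors", {
  tab <- random_table(n_species = 5, seed = 12, missing_frac = 0)
  expect_error(run_pca(tab, dims = 6), class = "lipidflux_data_error")
})
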