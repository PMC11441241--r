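#' @title Batch adjustment and principal component analysis
#' @description The two independently grown sets are a batch factor;
#'   before ordination they are removed with a parametric empirical-Bayes
#'   location/scale adjustment (the ComBat model) that preserves the
#'   condition covariate. PCA then runs on log2 intensities, centered and
#'   (by default) unit-scaled per species, and reports per-species
#'   squared-loading contributions to each dimension.
#' @name reduce
NULL

#' Presence filter for the PCA branch
#'
#' Retains species detected in at least `min_frac` of ALL biological
#' samples — a deliberately different rule from [presence_filter()], which
#' works within conditions. The boundary is inclusive ("at least 50%").
#'
#' @param table A `lipid_table`.
#' @param min_frac Minimum detection fraction over all non-blank samples.
#' @return A `lipid_table` at stage `"pca_filtered"`.
#' @export
pca_presence_filter <- function(table, min_frac = 0.5) {
  stopifnot(inherits(table, "lipid_table"))
  bio <- !table$samples$is_blank
  frac <- rowMeans(detection_matrix(table)[, bio, drop = FALSE])
  keep <- frac >= min_frac
  out <- append_log(table, "pca_presence_filter",
                    rownames(table$values)[!keep], frac[!keep])
  out <- drop_species(out, keep)
  advance_stage(out, "pca_filtered")
}

#' Complete remaining missing values
#'
#' Missing values that survive the PCA presence filter are completed so
#' that the batch adjustment and the SVD can run. Completion is flagged in
#' the filter log, never silent, and is the only place the pipeline fills
#' a missing value.
#'
#' @param table A `lipid_table`.
#' @param method `"half_min"` (half the species' smallest observed value,
#'   the default), `"zero"`, or `"row_median"`.
#' @return A complete `lipid_table` at stage `"completed"`.
#' @export
complete_missing <- function(table,
                             method = c("half_min", "zero", "row_median")) {
  method <- match.arg(method)
  stopifnot(inherits(table, "lipid_table"))
  v <- table$values
  n_filled <- rowSums(is.na(v))
  for (i in which(n_filled > 0L)) {
    fill <- switch(method,
      half_min = min(v[i, ], na.rm = TRUE) / 2,
      zero = 0,
      row_median = stats::median(v[i, ], na.rm = TRUE))
    v[i, is.na(v[i, ])] <- fill
  }
  out <- table
  out$values <- v
  out <- append_log(out, paste0("complete_", method),
                    rownames(v)[n_filled > 0L], n_filled[n_filled > 0L],
                    action = "completed")
  advance_stage(out, "completed")
}

# Parametric empirical-Bayes batch adjustment on a complete log2 matrix
# (species x samples). Normal prior on the batch location shifts,
# inverse-gamma prior on the batch scale factors; posterior means found by
# the standard fixed-point iteration.
combat_fit <- function(logx, batch, condition, tol = 1e-6, max_iter = 1000L) {
  batch <- as.factor(batch)
  condition <- as.factor(condition)
  n <- ncol(logx)
  batches <- levels(batch)
  n_batch <- length(batches)
  batch_idx <- lapply(batches, function(b) which(batch == b))
  n_per <- vapply(batch_idx, length, integer(1L))

  design <- stats::model.matrix(~ -1 + batch)
  if (nlevels(condition) > 1L) {
    design <- cbind(design, stats::model.matrix(~condition)[, -1, drop = FALSE])
  }
  # per-species OLS fit of batch means + condition effects
  B_hat <- solve(crossprod(design), t(design) %*% t(logx))
  grand_mean <- crossprod(n_per / n, B_hat[seq_len(n_batch), , drop = FALSE])
  var_pooled <- rowMeans((logx - t(design %*% B_hat))^2)
  zero_var <- var_pooled < .Machine$double.eps
  var_pooled[zero_var] <- 1  # flagged upstream; left unadjusted below

  stand_mean <- matrix(grand_mean, nrow(logx), n, byrow = FALSE)
  if (ncol(design) > n_batch) {
    mod_part <- design[, -(seq_len(n_batch)), drop = FALSE] %*%
      B_hat[-(seq_len(n_batch)), , drop = FALSE]
    stand_mean <- stand_mean + t(mod_part)
  }
  Z <- (logx - stand_mean) / sqrt(var_pooled)

  gamma_hat <- sapply(batch_idx, function(ix) rowMeans(Z[, ix, drop = FALSE]))
  delta_hat <- sapply(batch_idx, function(ix) {
    apply(Z[, ix, drop = FALSE], 1L, stats::var)
  })
  gamma_hat <- matrix(gamma_hat, ncol = n_batch)
  delta_hat <- matrix(delta_hat, ncol = n_batch)

  gamma_bar <- colMeans(gamma_hat)
  tau2 <- apply(gamma_hat, 2L, stats::var)
  # method-of-moments inverse-gamma hyperparameters
  V <- colMeans(delta_hat)
  S2 <- apply(delta_hat, 2L, stats::var)
  a_prior <- (2 * S2 + V^2) / S2
  b_prior <- (V * S2 + V^3) / S2

  gamma_star <- gamma_hat
  delta_star <- delta_hat
  for (j in seq_len(n_batch)) {
    nj <- n_per[j]
    g_old <- gamma_hat[, j]
    d_old <- delta_hat[, j]
    Zj <- Z[, batch_idx[[j]], drop = FALSE]
    for (it in seq_len(max_iter)) {
      g_new <- (nj * tau2[j] * gamma_hat[, j] + d_old * gamma_bar[j]) /
        (nj * tau2[j] + d_old)
      ss <- rowSums((Zj - g_new)^2)
      d_new <- (0.5 * ss + b_prior[j]) / (nj / 2 + a_prior[j] - 1)
      change <- max(abs(g_new - g_old) / pmax(abs(g_old), 1e-12),
                    abs(d_new - d_old) / pmax(abs(d_old), 1e-12))
      g_old <- g_new
      d_old <- d_new
      if (change < tol) break
    }
    gamma_star[, j] <- g_old
    delta_star[, j] <- d_old
  }

  adjusted <- Z
  for (j in seq_len(n_batch)) {
    ix <- batch_idx[[j]]
    adjusted[, ix] <- (Z[, ix, drop = FALSE] - gamma_star[, j]) /
      sqrt(delta_star[, j])
  }
  adjusted <- adjusted * sqrt(var_pooled) + stand_mean
  adjusted[zero_var, ] <- logx[zero_var, ]

  dimnames(gamma_star) <- dimnames(delta_star) <-
    list(rownames(logx), batches)
  list(adjusted = adjusted,
       model = structure(list(
         batches = batches,
         location = gamma_star, scale = sqrt(delta_star),
         gamma_bar = gamma_bar, tau2 = tau2,
         a_prior = a_prior, b_prior = b_prior,
         zero_variance_species = rownames(logx)[zero_var]),
         class = "batch_model"))
}

#' @export
print.batch_model <- function(x, ...) {
  cat(sprintf("<batch_model> %d batches, %d species\n",
              length(x$batches), nrow(x$location)))
  cat("  prior means (location):",
      paste(sprintf("%s=%.3f", x$batches, x$gamma_bar), collapse = ", "), "\n")
  if (length(x$zero_variance_species)) {
    cat("  left unadjusted (zero variance):",
        length(x$zero_variance_species), "species\n")
  }
  invisible(x)
}

#' Empirical-Bayes batch adjustment (ComBat model)
#'
#' Adjusts the two growth sets toward a common location and scale per
#' species using the parametric ComBat model: species are standardized
#' under a design that preserves the condition covariate, per-batch
#' location shifts get a normal prior and scale factors an inverse-gamma
#' prior, and posterior means are found by fixed-point iteration
#' (tolerance 1e-6, at most 1000 iterations). Values are log2-transformed
#' internally and back-transformed on output, so table dimensions and
#' positivity are preserved. A single batch returns the input unchanged.
#' Species with zero variance inside every batch cannot be standardized;
#' they are left unadjusted and flagged in the model.
#'
#' @param table A complete (no missing values) `lipid_table`.
#' @param batch_key Column of the sample metadata to use as batch,
#'   default `"set_id"`.
#' @return A list with `table` (the adjusted `lipid_table`, stage
#'   `"batch_adjusted"`) and `model` (a `batch_model` with the per-batch
#'   shifts, scale factors and shrinkage hyperparameters).
#' @export
batch_adjust <- function(table, batch_key = "set_id") {
  stopifnot(inherits(table, "lipid_table"))
  bio <- !table$samples$is_blank
  v <- table$values[, bio, drop = FALSE]
  if (anyNA(v)) {
    condition_error("batch adjustment needs a complete matrix; run complete_missing() first",
                    "lipidflux_data_error")
  }
  batch <- table$samples[[batch_key]][bio]
  condition <- table$samples$condition[bio]
  out <- table
  if (length(unique(batch)) < 2L) {
    out <- advance_stage(out, "batch_adjusted")
    return(list(table = out, model = NULL))
  }
  if (min(table(batch)) < 2L) {
    condition_error("each batch needs at least 2 samples",
                    "lipidflux_data_error")
  }
  fit <- combat_fit(log2(v), batch, condition)
  out$values[, bio] <- 2^fit$adjusted
  out <- advance_stage(out, "batch_adjusted")
  list(table = out, model = fit$model)
}

#' Principal component analysis with species contributions
#'
#' Computes the SVD of the centered (and by default per-species
#' unit-scaled) log2 intensity matrix over biological samples. Loadings
#' have unit-norm columns; `explained_frac` are the eigenvalue shares of
#' total variance; the contribution of species i to dimension d is its
#' squared loading share, so each contributions column sums to 1.
#'
#' @param table A complete `lipid_table`.
#' @param dims Number of dimensions to report (at most
#'   `min(n_samples - 1, n_species)`).
#' @param scale. Unit-scale each species (default TRUE, so high-abundance
#'   classes cannot dominate purely by magnitude). Zero-variance species
#'   are centered only.
#' @param log2_transform Log2-transform intensities first (default TRUE).
#' @return An object of class `lipid_pca`: `scores` (samples x dims),
#'   `loadings` (species x dims), `explained_frac`, `contributions`
#'   (species x dims, columns summing to 1), plus `samples` metadata.
#' @export
run_pca <- function(table, dims = 2L, scale. = TRUE, log2_transform = TRUE) {
  stopifnot(inherits(table, "lipid_table"))
  bio <- !table$samples$is_blank
  v <- table$values[, bio, drop = FALSE]
  if (anyNA(v)) {
    condition_error("PCA needs a complete matrix; run complete_missing() first",
                    "lipidflux_data_error")
  }
  x <- if (log2_transform) log2(v) else v
  x <- t(x)  # samples x species
  x <- scale(x, center = TRUE, scale = FALSE)
  if (scale.) {
    sds <- apply(x, 2L, stats::sd)
    sds[sds < .Machine$double.eps] <- 1
    x <- sweep(x, 2L, sds, `/`)
  }
  max_dims <- min(nrow(x) - 1L, ncol(x))
  if (dims > max_dims) {
    condition_error(sprintf("dims = %d exceeds the maximum rank %d",
                            dims, max_dims), "lipidflux_data_error")
  }
  sv <- svd(x)
  ev <- sv$d^2
  explained <- ev / sum(ev)
  keep <- seq_len(max_dims)
  scores <- sv$u %*% diag(sv$d, length(sv$d))
  loadings <- sv$v
  dn <- paste0("PC", keep)
  scores <- scores[, keep, drop = FALSE]
  loadings <- loadings[, keep, drop = FALSE]
  dimnames(scores) <- list(rownames(x), dn)
  dimnames(loadings) <- list(colnames(x), dn)
  contributions <- sweep(loadings^2, 2L, colSums(loadings^2), `/`)
  structure(list(scores = scores[, seq_len(dims), drop = FALSE],
                 loadings = loadings[, seq_len(dims), drop = FALSE],
                 explained_frac = explained[seq_len(dims)],
                 contributions = contributions[, seq_len(dims), drop = FALSE],
                 explained_all = explained[keep],
                 scores_all = scores,
                 loadings_all = loadings,
                 centered = x,
                 samples = table$samples[bio, , drop = FALSE],
                 species = table$species),
            class = "lipid_pca")
}

#' @export
print.lipid_pca <- function(x, ...) {
  cat(sprintf("<lipid_pca> %d samples x %d species, %d dims reported\n",
              nrow(x$scores), nrow(x$loadings), ncol(x$scores)))
  cat("  explained variance:",
      paste(sprintf("%s %.1f%%", colnames(x$scores),
                    100 * x$explained_frac), collapse = ", "), "\n")
  invisible(x)
}

#' Scatter plot of the first two PCA dimensions
#'
#' @param x A `lipid_pca`.
#' @param dims Two dimensions to draw.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.lipid_pca <- function(x, dims = c(1L, 2L), ...) {
  cond <- factor(x$samples$condition)
  graphics::plot(x$scores[, dims[1L]], x$scores[, dims[2L]],
                 col = as.integer(cond) + 1L, pch = 19,
                 xlab = sprintf("PC%d (%.1f%%)", dims[1L],
                                100 * x$explained_frac[dims[1L]]),
                 ylab = sprintf("PC%d (%.1f%%)", dims[2L],
                                100 * x$explained_frac[dims[2L]]),
                 ...)
  graphics::legend("topright", legend = levels(cond), pch = 19,
                   col = seq_along(levels(cond)) + 1L, bty = "n")
  invisible(x)
}
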