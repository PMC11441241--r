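#' @title Differential statistics: exclusives, double bonds, acyl
#'   profiles, multiple t-tests
#' @description Per-species and aggregated condition contrasts: species
#'   detected exclusively under one condition, double-bond histograms per
#'   class, fatty-acyl-level abundance aggregation, Shapiro-Wilk normality
#'   flags, Welch t-tests on log2 abundances with Holm-Sidak step-down
#'   correction.
#' @name differential
NULL

#' Condition-exclusive species
#'
#' A species is exclusive to condition X when it is detected in at least
#' `min_frac` of the X samples of at least one set and in zero samples of
#' the other condition. The threshold mirrors the presence filter; the two
#' exclusive sets are disjoint by construction.
#'
#' @param table A `lipid_table` with condition metadata (normally
#'   presence-filtered).
#' @param min_frac Detection fraction required within one set of the
#'   owning condition (default 0.5).
#' @return A named list of character vectors, one per condition.
#' @export
exclusive_species <- function(table, min_frac = 0.5) {
  stopifnot(inherits(table, "lipid_table"))
  bio <- !table$samples$is_blank
  det <- detection_matrix(table)[, bio, drop = FALSE]
  meta <- table$samples[bio, , drop = FALSE]
  conditions <- unique(meta$condition)
  stopifnot(length(conditions) == 2L)
  out <- lapply(conditions, function(cond) {
    own <- meta$condition == cond
    frac_by_set <- sapply(unique(meta$set_id[own]), function(s) {
      rowMeans(det[, own & meta$set_id == s, drop = FALSE])
    })
    frac_by_set <- matrix(frac_by_set, nrow = nrow(det))
    present_enough <- apply(frac_by_set, 1L, max) >= min_frac
    absent_other <- rowSums(det[, !own, drop = FALSE]) == 0L
    rownames(det)[present_enough & absent_other]
  })
  stats::setNames(out, conditions)
}

#' Double-bond profile of a lipid class
#'
#' Counts, per condition, the distinct detected species of a class at
#' each total double-bond number (detection = non-missing in at least one
#' sample of the condition).
#'
#' @param table A `lipid_table`.
#' @param class_code Lipid class to profile, e.g. `"TG"`.
#' @return Data frame with `double_bonds` and one count column per
#'   condition; bin totals equal the number of detected species.
#' @export
double_bond_profile <- function(table, class_code) {
  stopifnot(inherits(table, "lipid_table"))
  sel <- table$species$class_code == class_code
  db <- table$species$sum_double_bonds[sel]
  det <- detection_matrix(table)[sel, , drop = FALSE]
  meta <- table$samples
  bio <- !meta$is_blank
  conditions <- unique(meta$condition[bio])
  bins <- if (length(db)) seq(0L, max(db)) else integer(0)
  out <- data.frame(double_bonds = bins)
  for (cond in conditions) {
    cols <- bio & meta$condition == cond
    detected <- rowSums(det[, cols, drop = FALSE]) >= 1L
    out[[cond]] <- vapply(bins, function(b) sum(detected & db == b),
                          integer(1L))
  }
  out
}

#' Fatty-acyl abundance profile of a class
#'
#' For every distinct acyl occurring in the class's molecular species, the
#' per-sample abundance is the sum over species containing that acyl —
#' counted once per species regardless of multiplicity (a species with a
#' repeated chain contributes its abundance once), matching counts of
#' "species esterified with" an acyl. A multiplicity-weighted mode is
#' available.
#'
#' @param table A `lipid_table`.
#' @param class_code Class to profile.
#' @param weighted Multiply by chain multiplicity (default FALSE).
#' @return A numeric acyl-by-samples matrix (rownames `"C:D"`). Errors if
#'   the class has only sum-composition species.
#' @export
acyl_profile <- function(table, class_code, weighted = FALSE) {
  stopifnot(inherits(table, "lipid_table"))
  sel <- which(table$species$class_code == class_code)
  mol <- sel[table$species$level[sel] == "molecular_species"]
  if (length(sel) > 0L && length(mol) == 0L) {
    condition_error(sprintf(
      "class %s has only sum-composition species; acyl profiling needs molecular species",
      class_code), "lipidflux_undefined_query_error")
  }
  chains <- table$species$chains[mol]
  acyls <- sort(unique(unlist(lapply(chains, function(ch) {
    sprintf("%d:%d", ch[, "carbons"], ch[, "double_bonds"])
  }))))
  v <- table$values[mol, , drop = FALSE]
  v0 <- v
  v0[is.na(v0)] <- 0
  out <- matrix(0, nrow = length(acyls), ncol = ncol(v),
                dimnames = list(acyls, colnames(v)))
  for (i in seq_along(mol)) {
    ch <- sprintf("%d:%d", chains[[i]][, "carbons"],
                  chains[[i]][, "double_bonds"])
    w <- if (weighted) table(ch) else table(unique(ch))
    out[names(w), ] <- out[names(w), , drop = FALSE] +
      as.integer(w) * rep(v0[i, ], each = length(w))
  }
  out
}

#' Shapiro-Wilk normality check
#'
#' @param values Numeric vector, length >= 3 and non-constant.
#' @return A list with `W`, `p_value` and `flag` (`TRUE` when p > 0.05,
#'   i.e. no evidence against normality).
#' @export
normality_check <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3L) {
    condition_error("normality check needs at least 3 values",
                    "lipidflux_data_error")
  }
  if (stats::sd(values) == 0) {
    condition_error("normality check is undefined for constant input",
                    "lipidflux_data_error")
  }
  sw <- stats::shapiro.test(values)
  list(W = unname(sw$statistic), p_value = sw$p.value,
       flag = sw$p.value > 0.05)
}

#' Holm-Sidak step-down adjustment
#'
#' Sorts the p-values ascending and sets
#' `adj_(i) = max_{j <= i} (1 - (1 - p_(j))^(m - j + 1))`, clipped to 1,
#' returned in the original order. Output is always >= the input and
#' monotone in rank order. `NA`s are passed through and excluded from the
#' family size.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the original order.
#' @examples
#' holm_sidak(c(0.01, 0.04))  # 0.0199, 0.04
#' @export
holm_sidak <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    condition_error("p-values must lie in [0, 1]", "lipidflux_data_error")
  }
  out <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m == 0L) return(out)
  ord <- order(pv)
  sorted <- pv[ord]
  adj <- 1 - (1 - sorted)^(m - seq_len(m) + 1)
  adj <- cummax(adj)
  adj <- pmin(adj, 1)
  res <- numeric(m)
  res[ord] <- adj
  out[ok] <- res
  out
}

significance_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "***",
                              ifelse(p < 0.01, "**",
                                     ifelse(p < 0.05, "*", ""))))
}

# Vectorized Welch t-tests over the rows of a matrix (log2 scale input).
welch_rows <- function(x, group1, group2) {
  x1 <- x[, group1, drop = FALSE]
  x2 <- x[, group2, drop = FALSE]
  n1 <- rowSums(!is.na(x1))
  n2 <- rowSums(!is.na(x2))
  m1 <- rowMeans(x1, na.rm = TRUE)
  m2 <- rowMeans(x2, na.rm = TRUE)
  v1 <- apply(x1, 1L, stats::var, na.rm = TRUE)
  v2 <- apply(x2, 1L, stats::var, na.rm = TRUE)
  se2 <- v1 / n1 + v2 / n2
  t_stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  # identical groups: zero difference and zero spread is a p of 1, not NaN
  degenerate <- !is.na(se2) & se2 == 0 & !is.na(m1 - m2) & (m1 - m2) == 0
  t_stat[degenerate] <- 0
  p[degenerate] <- 1
  data.frame(mean1 = m1, mean2 = m2, diff = m1 - m2, t_stat = t_stat,
             df = df, p_raw = p, n1 = n1, n2 = n2, var1 = v1, var2 = v2)
}

#' Multiple Welch t-tests with Holm-Sidak correction
#'
#' Tests every unit (species row, or any named abundance matrix such as an
#' acyl profile) for a hypoxia-vs-control difference: two-sided Welch
#' t-test on log2 abundances, Holm-Sidak adjustment across the family of
#' testable units, significance stars at 0.05 / 0.01 / 0.001. Units with
#' fewer than 2 non-missing values per condition, or with zero variance in
#' both groups and unequal means, are skipped and flagged. Each group also
#' gets a Shapiro-Wilk normality flag (NA when not computable).
#'
#' @param x A `lipid_table`, or a units-by-samples numeric matrix of
#'   abundances (not yet log-transformed).
#' @param samples Sample metadata (taken from the table when `x` is a
#'   `lipid_table`).
#' @param conditions Length-2 character vector: test `conditions[1]`
#'   against the control `conditions[2]`.
#' @param log2_transform Log2-transform abundances first (default TRUE).
#' @return Data frame with one row per unit: `unit`, `log2_fold_change`
#'   (first condition vs control), `t_stat`, `p_raw`, `p_adj`, `stars`,
#'   `normal_1`, `normal_2`, `skipped`.
#' @export
multi_ttest <- function(x, samples = NULL,
                        conditions = c("hypoxia", "control"),
                        log2_transform = TRUE) {
  if (inherits(x, "lipid_table")) {
    samples <- x$samples
    x <- x$values
  }
  stopifnot(is.matrix(x), !is.null(samples))
  bio <- !samples$is_blank
  x <- x[, bio, drop = FALSE]
  meta <- samples[bio, , drop = FALSE]
  g1 <- meta$condition == conditions[1L]
  g2 <- meta$condition == conditions[2L]
  stopifnot(any(g1), any(g2))
  lx <- if (log2_transform) log2(x) else x
  w <- welch_rows(lx, g1, g2)
  zero_spread <- !is.na(w$var1) & !is.na(w$var2) & w$var1 == 0 & w$var2 == 0
  skipped <- w$n1 < 2L | w$n2 < 2L | zero_spread
  p_raw <- w$p_raw
  p_raw[skipped] <- NA_real_
  p_adj <- holm_sidak(p_raw)
  normal_flag <- function(rows, cols) {
    vapply(seq_len(nrow(lx)), function(i) {
      v <- lx[i, cols]
      v <- v[!is.na(v) & is.finite(v)]
      if (length(v) < 3L || stats::sd(v) == 0) return(NA)
      stats::shapiro.test(v)$p.value > 0.05
    }, logical(1L))
  }
  data.frame(
    unit = rownames(x),
    log2_fold_change = w$diff,
    t_stat = ifelse(skipped, NA_real_, w$t_stat),
    p_raw = p_raw,
    p_adj = p_adj,
    stars = significance_stars(p_adj),
    normal_1 = normal_flag(NULL, g1),
    normal_2 = normal_flag(NULL, g2),
    skipped = skipped,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
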