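#' @title Dimension-spanning species and lipid-class enrichment
#' @description A species "spans" a PCA dimension when its squared-loading
#'   contribution exceeds twice the uniform expectation 1/p (strictly).
#'   Lipid classes are then tested one-vs-rest for over- or
#'   under-representation among the spanning species with Fisher's exact
#'   test (two-sided, minimum-likelihood rule).
#' @name enrich
NULL

#' Species spanning a PCA dimension
#'
#' Species i spans dimension `dim` iff `contributions[i, dim] > fold / p`,
#' where p is the number of species in the PCA and the inequality is
#' strict: a species at exactly the threshold does not span.
#'
#' @param pca A `lipid_pca`.
#' @param dim Dimension index.
#' @param fold Multiple of the uniform expected contribution (default 2).
#' @return Character vector of spanning species names.
#' @export
spanning_species <- function(pca, dim = 1L, fold = 2) {
  stopifnot(inherits(pca, "lipid_pca"), dim >= 1L, dim <= ncol(pca$contributions))
  p <- nrow(pca$contributions)
  stopifnot(p > 0L)
  rownames(pca$contributions)[pca$contributions[, dim] > fold / p]
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact two-sided test by the minimum-likelihood rule: the p-value is the
#' sum of hypergeometric probabilities, over all tables with the observed
#' margins, that do not exceed the probability of the observed table. The
#' odds ratio is the sample odds ratio `(a*d)/(b*c)`, infinite when
#' `b*c = 0`.
#'
#' @param a,b,c,d Non-negative integer cell counts: `a` = spanning and in
#'   class, `b` = spanning and other, `c` = non-spanning and in class,
#'   `d` = non-spanning and other.
#' @return A list with `odds_ratio` and `p_value`.
#' @examples
#' fisher_exact(2, 0, 0, 2)$p_value  # 1/3
#' @export
fisher_exact <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    condition_error("cell counts must be non-negative integers",
                    "lipidflux_data_error")
  }
  if (sum(counts) == 0) {
    condition_error("the table must contain at least one observation",
                    "lipidflux_data_error")
  }
  m <- a + b  # spanning margin
  n <- c + d
  k <- a + c  # class margin
  support <- max(0L, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  # tolerance guards against ties lost to floating point, as is standard
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  odds_ratio <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else {
    (a * d) / (b * c)
  }
  list(odds_ratio = odds_ratio, p_value = min(p, 1))
}

#' Class enrichment among spanning species
#'
#' One Fisher test per lipid class (or category) with at least one member
#' in the universe: spanning-and-class vs spanning-and-other vs
#' non-spanning counterparts. Direction is `enriched` when the odds ratio
#' exceeds 1 and p < alpha, `depleted` when it is below 1 and p < alpha,
#' otherwise `none`. No correction across classes by default; an optional
#' Benjamini-Hochberg column can be added.
#'
#' @param spanning Character vector of spanning species names (subset of
#'   the universe).
#' @param universe Species annotation data frame (e.g. `table$species` or
#'   `pca$species`) with columns `name` and the grouping column.
#' @param by Grouping column: `"class_code"` (default) or `"category"`.
#' @param alpha Significance level for calling a direction.
#' @param adjust Add a BH-adjusted p-value column (default FALSE).
#' @return Data frame with one row per class: `class_code`, `a,b,c,d`,
#'   `odds_ratio`, `p_value`, `direction` (and `p_adj` when `adjust`).
#' @export
class_enrichment <- function(spanning, universe, by = "class_code",
                             alpha = 0.05, adjust = FALSE) {
  stopifnot(all(spanning %in% universe$name))
  groups <- universe[[by]]
  in_span <- universe$name %in% spanning
  classes <- sort(unique(groups))
  res <- lapply(classes, function(cl) {
    in_cl <- groups == cl
    a <- sum(in_span & in_cl)
    b <- sum(in_span & !in_cl)
    c_ <- sum(!in_span & in_cl)
    d <- sum(!in_span & !in_cl)
    ft <- fisher_exact(a, b, c_, d)
    data.frame(class_code = cl, a = a, b = b, c = c_, d = d,
               odds_ratio = ft$odds_ratio, p_value = ft$p_value,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$direction <- "none"
  sig <- res$p_value < alpha
  res$direction[sig & res$odds_ratio > 1] <- "enriched"
  res$direction[sig & res$odds_ratio < 1] <- "depleted"
  if (adjust) res$p_adj <- stats::p.adjust(res$p_value, method = "BH")
  res
}

#' Condition-separating dimension
#'
#' The dimension whose condition score means differ most in absolute
#' value — the quantitative counterpart of reading the separation off the
#' score plot.
#'
#' @param pca A `lipid_pca` whose samples carry a two-level `condition`.
#' @return Integer dimension index.
#' @export
separating_dimension <- function(pca) {
  stopifnot(inherits(pca, "lipid_pca"))
  cond <- pca$samples$condition
  lv <- unique(cond)
  stopifnot(length(lv) == 2L)
  gap <- abs(colMeans(pca$scores[cond == lv[1L], , drop = FALSE]) -
             colMeans(pca$scores[cond == lv[2L], , drop = FALSE]))
  which.max(gap)
}
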