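# Statistical toolkit: tissue-specificity tau, two-proportion z-test,
# chi-square, two-sided Fisher's exact test, odds ratios, Pearson
# correlation, and BH-adjusted gene-set enrichment.

#' Tissue-specificity index tau
#'
#' For each gene with expression `x` over `n >= 2` tissues,
#' `tau = sum_i(1 - x_i / max(x)) / (n - 1)`: 0 for uniformly (broadly)
#' expressed genes, 1 for expression confined to a single tissue.
#' Computed on the linear scale by default; `log` applies log2(x + 1)
#' first.
#'
#' @param expr non-negative matrix, genes x tissues.
#' @param log apply log2(x + 1) before computing tau. Default `FALSE`.
#' @return named numeric vector of tau values; genes with all-zero
#'   expression are `NA` (undefined).
#' @export
tau <- function(expr, log = FALSE) {
  m <- as.matrix(expr)
  if (ncol(m) < 2) stop("tau needs at least two tissues")
  if (any(m < 0)) stop("negative expression values")
  if (log) m <- log2(m + 1)
  mx <- apply(m, 1, max)
  out <- ifelse(mx > 0, rowSums(1 - m / mx) / (ncol(m) - 1), NA_real_)
  names(out) <- rownames(m)
  out
}

#' Two-proportion z-test
#'
#' Pooled-proportion z statistic for comparing `k1/n1` with `k2/n2`,
#' with a two-sided normal p-value.  With a pooled proportion of exactly
#' 0 or 1 the statistic is 0 and p is 1.  On a 2x2 table, z squared
#' equals the Pearson chi-square statistic without continuity correction.
#'
#' @param k1,n1,k2,n2 successes and totals in the two groups.
#' @return list with `statistic` (z), `pvalue`, `method`.
#' @export
two_proportion_ztest <- function(k1, n1, k2, n2) {
  stopifnot(n1 > 0, n2 > 0, k1 >= 0, k1 <= n1, k2 >= 0, k2 <= n2)
  p_pool <- (k1 + k2) / (n1 + n2)
  if (p_pool == 0 || p_pool == 1) {
    return(list(statistic = 0, pvalue = 1, method = "ztest"))
  }
  z <- unname((k1 / n1 - k2 / n2) /
                sqrt(p_pool * (1 - p_pool) * (1 / n1 + 1 / n2)))
  list(statistic = z, pvalue = 2 * stats::pnorm(-abs(z)), method = "ztest")
}

#' Pearson chi-square test on a 2 x k table
#'
#' Pearson chi-square without continuity correction, df = k - 1,
#' upper-tail p-value (wraps [stats::chisq.test()]).
#'
#' @param table 2 x k matrix of non-negative counts with all row and
#'   column marginals positive.
#' @return list with `statistic`, `pvalue`, `df`, `method`.
#' @export
chi2_test <- function(table) {
  m <- as.matrix(table)
  stopifnot(nrow(m) == 2, ncol(m) >= 2, all(m >= 0))
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("chi-square test undefined: zero marginal")
  }
  res <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(res$statistic), pvalue = unname(res$p.value),
       df = unname(res$parameter), method = "chi2")
}

#' Two-sided Fisher's exact test on a 2 x 2 table
#'
#' Exact two-sided p-value: the sum, over all tables with the observed
#' marginals, of hypergeometric probabilities no larger than that of the
#' observed table (with the conventional relative tolerance 1 + 1e-7 for
#' floating-point ties).
#'
#' @param table 2 x 2 matrix of non-negative integer counts.
#' @return list with `statistic` (the observed table probability),
#'   `pvalue`, `method`.
#' @export
fisher_exact <- function(table) {
  m <- as.matrix(table)
  stopifnot(nrow(m) == 2, ncol(m) == 2, all(m >= 0))
  a <- m[1, 1]
  K <- sum(m[1, ])   # row-1 total (white balls)
  n2 <- sum(m[2, ])  # row-2 total
  cs <- sum(m[, 1])  # column-1 total (drawn)
  support <- max(0, cs - n2):min(K, cs)
  d <- stats::dhyper(support, K, n2, cs)
  d_obs <- stats::dhyper(a, K, n2, cs)
  p <- min(1, sum(d[d <= d_obs * (1 + 1e-7)]))
  list(statistic = d_obs, pvalue = p, method = "fisher")
}

#' Odds ratio of a 2 x 2 table
#'
#' Cross-product odds ratio `(a*d)/(b*c)`.  When either off-diagonal cell
#' is zero the Haldane-Anscombe correction (+0.5 to every cell) is
#' applied and the result carries attribute `corrected = TRUE`.
#'
#' @param table 2 x 2 matrix of non-negative counts.
#' @return numeric odds ratio, with a `corrected` attribute.
#' @export
odds_ratio <- function(table) {
  m <- as.matrix(table)
  stopifnot(nrow(m) == 2, ncol(m) == 2, all(m >= 0))
  corrected <- m[1, 2] == 0 || m[2, 1] == 0
  if (corrected) m <- m + 0.5
  structure((m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1]),
            corrected = corrected)
}

#' Pearson correlation with t-based p-value
#'
#' Pearson's r and the two-sided p-value from the t transform with n - 2
#' degrees of freedom (wraps [stats::cor.test()]).  Pairs with a missing
#' value in either vector are excluded beforehand; with zero variance in
#' either vector the result is undefined (`NA`).
#'
#' @param x,y equal-length numeric vectors (>= 3 complete pairs).
#' @return list with `statistic` (r), `pvalue`, `n`, `method`.
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(statistic = NA_real_, pvalue = NA_real_, n = length(x),
                method = "pearson"))
  }
  res <- stats::cor.test(x, y, method = "pearson")
  list(statistic = unname(res$estimate), pvalue = res$p.value,
       n = length(x), method = "pearson")
}

#' Gene-set enrichment by Fisher's exact test
#'
#' For each named gene set (intersected with the universe), builds the
#' 2x2 table of in-group/out-group by in-set/out-set membership, computes
#' the two-sided Fisher p-value and odds ratio, and adjusts p-values
#' across sets with Benjamini-Hochberg.  Significance is called at
#' adjusted p < 0.05.
#'
#' @param group_genes character vector, a subset of `universe`.
#' @param sets named list of character vectors.
#' @param universe character vector of all eligible genes (defaults in
#'   pipeline use to the filtered gene set).
#' @param alpha adjusted-p cutoff (exclusive). Default 0.05.
#' @return data.frame with set_id, set_size, overlap, odds_ratio, pvalue,
#'   adjusted_p, significant.
#' @export
geneset_enrichment <- function(group_genes, sets, universe, alpha = 0.05) {
  if (length(universe) == 0) stop("empty universe")
  if (!all(group_genes %in% universe)) {
    stop("group_genes must be a subset of the universe")
  }
  group_genes <- unique(group_genes)
  res <- lapply(names(sets), function(id) {
    s <- intersect(sets[[id]], universe)
    a <- length(intersect(group_genes, s))
    b <- length(group_genes) - a
    c <- length(s) - a
    d <- length(universe) - a - b - c
    tab <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
    data.frame(set_id = id, set_size = length(s), overlap = a,
               odds_ratio = as.numeric(odds_ratio(tab)),
               pvalue = fisher_exact(tab)$pvalue,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$adjusted_p <- bh_adjust(out$pvalue)
  out$significant <- out$adjusted_p < alpha
  out[order(out$pvalue, out$set_id), , drop = FALSE]
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment (wraps
#' [stats::p.adjust()] with `method = "BH"`), after validating that all
#' inputs lie in `[0, 1]`.
#'
#' @param pvalues numeric vector of p-values.
#' @return adjusted p-values in the original order, capped at 1.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}
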