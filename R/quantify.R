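# Count normalisation and differential criteria: TPM, TMM scaling
# factors, m6A level (IP/input), an exact two-rate test, and the
# p < 0.05 & |log2FC| > 1 gene-calling rule.

#' Read a count table with its sample sheet
#'
#' Count tables are TSV files whose first column is `gene_id`, second
#' column `length` (spliced nt), and remaining columns one sample each.
#' The sample sheet maps sample -> role (IP/input) and condition.
#'
#' @param counts_path TSV of counts.
#' @param samples_path TSV with columns `sample`, `role`, and optional
#'   further annotation (e.g. `stage`, `replicate`).
#' @return list with `counts` (integer matrix, genes x samples),
#'   `lengths` (named vector), `samples` (data.frame).
#' @export
read_count_table <- function(counts_path, samples_path) {
  tab <- utils::read.table(counts_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(colnames(tab)[1:2] == c("gene_id", "length"))
  counts <- as.matrix(tab[, -(1:2), drop = FALSE])
  rownames(counts) <- tab$gene_id
  samples <- utils::read.table(samples_path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "role") %in% colnames(samples)))
  missing <- setdiff(colnames(counts), samples$sample)
  if (length(missing) > 0) stop("samples without role: ",
                                paste(missing, collapse = ", "))
  list(counts = counts,
       lengths = structure(tab$length, names = tab$gene_id),
       samples = samples)
}

#' Transcripts-per-million normalisation
#'
#' TPM for gene g in a sample: `counts_g * 1e6 / (length_g * sum_j(counts_j
#' / length_j))`, so each column sums to one million over genes with a
#' defined length.
#'
#' @param counts non-negative matrix (genes x samples) or vector.
#' @param lengths per-gene feature lengths in nt (> 0), recycled across
#'   samples.
#' @return matrix (or vector) of TPM values.
#' @export
tpm <- function(counts, lengths) {
  vec <- is.null(dim(counts))
  m <- as.matrix(counts)
  if (length(lengths) != nrow(m)) stop("lengths must match genes")
  if (any(lengths <= 0)) stop("feature lengths must be positive")
  if (any(m < 0)) stop("negative counts")
  rate <- m / lengths
  denom <- colSums(rate)
  zero <- denom == 0
  if (any(zero)) {
    stop("all-zero sample(s): ",
         paste(colnames(m)[zero] %||% which(zero), collapse = ", "))
  }
  out <- sweep(rate, 2, denom, "/") * 1e6
  if (vec) out[, 1] else out
}

#' Trimmed mean of M-values scaling factors
#'
#' Between-sample scaling factors computed as the weighted trimmed mean of
#' per-gene log2 count ratios against a reference sample: genes zero in
#' either sample are removed, the most extreme 30% of M-values (log
#' ratios) and 5% of A-values (average log abundance) are trimmed from
#' each tail, the remainder is averaged with inverse-variance binomial
#' weights computed on relative abundances (scale-invariant, so a pure
#' depth change is absorbed exactly), and the resulting factors are
#' rescaled to geometric mean 1.
#' The factor is a multiplier on counts, so a sample sequenced twice as
#' deeply gets a factor half as large: pure library-size scaling is
#' absorbed into the scaled sample's factor.
#'
#' The reference is auto-chosen as the sample whose upper-quartile count
#' fraction is closest to the across-sample mean.
#'
#' @param counts non-negative matrix, genes x samples (>= 2 samples).
#' @param ref_sample column name/index of the reference, or `NULL` (auto).
#' @param logratio_trim,abundance_trim tail trim fractions for M and A.
#' @return named numeric vector of factors with geometric mean 1.
#' @export
tmm_factors <- function(counts, ref_sample = NULL,
                        logratio_trim = 0.3, abundance_trim = 0.05) {
  m <- as.matrix(counts)
  if (ncol(m) < 2) stop("TMM needs at least two samples")
  lib <- colSums(m)
  if (is.null(ref_sample)) {
    uq <- apply(m, 2, function(x) stats::quantile(x, 0.75)) / lib
    ref <- which.min(abs(uq - mean(uq)))
  } else {
    ref <- if (is.character(ref_sample)) match(ref_sample, colnames(m)) else ref_sample
    if (is.na(ref)) stop("unknown reference sample: ", ref_sample)
  }
  xr <- m[, ref]
  f <- vapply(seq_len(ncol(m)), function(s) {
    if (s == ref) return(1)
    xs <- m[, s]
    ok <- xs > 0 & xr > 0
    if (!any(ok)) return(1)
    # M, A and the weights are computed on relative abundances, which are
    # invariant under library-size scaling; the (constant) library-size
    # log-ratio is added back analytically afterwards.  This makes pure
    # depth changes absorb into the factor exactly, untouched by
    # floating-point tie-breaking in the rank trims.
    ps <- xs[ok] / lib[s]
    pr <- xr[ok] / lib[ref]
    M <- log2(ps) - log2(pr)
    A <- (log2(ps) + log2(pr)) / 2
    w <- 1 / ((1 - ps) / ps + (1 - pr) / pr)  # binomial variance of M
    n <- length(M)
    loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * abundance_trim) + 1; hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    if (sum(keep) < 10) {
      warning("fewer than 10 genes survive TMM trimming for sample ", s,
              "; using untrimmed mean")
      keep <- rep(TRUE, n)
    }
    2^(-sum(M[keep] * w[keep]) / sum(w[keep])) * lib[ref] / lib[s]
  }, 0)
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(m)
  f
}

#' m6A level as IP / input
#'
#' Per-gene m6A level: normalised IP value divided by normalised input
#' value.  Genes with zero input are flagged `input_too_low` and carry an
#' `NA` level (excluded from downstream correlations) rather than an
#' infinite or pseudocounted ratio.
#'
#' @param ip,input named numeric vectors of normalised values (e.g. TPM)
#'   over the same gene universe.
#' @return data.frame with `gene_id`, `level`, `flag`.
#' @export
m6a_level <- function(ip, input) {
  if (!setequal(names(ip), names(input))) {
    diff <- c(setdiff(names(ip), names(input)),
              setdiff(names(input), names(ip)))
    stop("mismatched gene universes: ", paste(utils::head(diff, 10), collapse = ", "))
  }
  input <- input[names(ip)]
  ok <- input > 0
  data.frame(gene_id = names(ip),
             level = ifelse(ok, ip / input, NA_real_),
             flag = ifelse(ok, "ok", "input_too_low"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Exact rate-ratio test for two counts
#'
#' Compares two counts with known scales (e.g. effective library sizes)
#' using the exact conditional binomial test: given `countsA + countsB`
#' events, `countsA` is Binomial with success probability
#' `scaleA / (scaleA + scaleB)` under equal rates.  The two-sided p-value
#' doubles the smaller tail (capped at 1).  The fold change uses a 0.5
#' pseudocount: `log2(((countsA + 0.5)/scaleA) / ((countsB + 0.5)/scaleB))`.
#' Vectorised over genes.
#'
#' @param countsA,countsB non-negative integer vectors.
#' @param scaleA,scaleB positive scales.
#' @return data.frame with `log2fc`, `pvalue`.
#' @export
rate_ratio_test <- function(countsA, countsB, scaleA = 1, scaleB = 1) {
  stopifnot(all(countsA >= 0), all(countsB >= 0),
            all(scaleA > 0), all(scaleB > 0))
  n <- countsA + countsB
  p0 <- scaleA / (scaleA + scaleB)
  lfc <- log2(((countsA + 0.5) / scaleA) / ((countsB + 0.5) / scaleB))
  lower <- stats::pbinom(countsA, n, p0)
  upper <- stats::pbinom(countsA - 1, n, p0, lower.tail = FALSE)
  p <- pmin(1, 2 * pmin(lower, upper))
  zero <- n == 0
  lfc[zero] <- 0
  p[zero] <- 1
  data.frame(log2fc = lfc, pvalue = p)
}

#' Call differential genes
#'
#' Applies the significance rule used for both differential expression and
#' differential methylation: a gene is significant iff `pvalue < 0.05`
#' and `|log2fc| > 1`, both strict.
#'
#' @param results data.frame with columns `gene_id`, `log2fc`, `pvalue`.
#' @param alpha,min_lfc thresholds (exclusive).
#' @return the input with a logical `significant` column appended.
#' @export
differential_genes <- function(results, alpha = 0.05, min_lfc = 1) {
  stopifnot(all(c("gene_id", "log2fc", "pvalue") %in% colnames(results)))
  results$significant <- results$pvalue < alpha & abs(results$log2fc) > min_lfc
  results
}
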