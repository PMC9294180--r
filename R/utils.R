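# Internal helpers shared across modules.
#
# All genomic intervals inside the package are 0-based, half-open (BED
# convention).  GTF records (1-based, closed) are converted on read; IRanges
# objects (1-based, closed) are converted at the boundary of every call into
# the IRanges/GenomicRanges stack.

GROUPS <- c("NMG", "5MG", "3MG", "CMG", "SMG")

REGION_WINDOWS <- c(fiveUTR = 10L, CDS = 20L, threeUTR = 20L)
N_WINDOWS <- 50L
WINDOW_OFFSET <- c(fiveUTR = 0L, CDS = 10L, threeUTR = 30L)

# meta-region column blocks used when labelling k-means centroids
LABEL_COLS <- list(
  fiveUTR = 1:10,
  cds_body = 11:27,
  stop_flank = 28:32,
  threeUTR_body = 33:50
)

#' @importFrom IRanges IRanges
ir0 <- function(start, end) {
  # 0-based half-open -> IRanges (1-based closed)
  IRanges::IRanges(start = as.integer(start) + 1L, end = as.integer(end))
}

#' @importFrom GenomicRanges GRanges
gr0 <- function(chrom, start, end, strand = "*") {
  GenomicRanges::GRanges(seqnames = chrom, ranges = ir0(start, end),
                         strand = strand)
}

#' Window sizes for a spliced region
#'
#' Splits `len` spliced bases into `n` windows of near-equal size; the
#' remainder bases are distributed one per window starting from the 5' end,
#' so windowing is deterministic.
#' @noRd
window_sizes <- function(len, n) {
  base <- len %/% n
  extra <- len %% n
  base + as.integer(seq_len(n) <= extra)
}

# cumulative window breaks: c(0, b1, ..., bn) with bn == len
window_breaks <- function(len, n) {
  c(0L, cumsum(window_sizes(len, n)))
}

# 1-based window index of a 0-based position within its region
window_of <- function(pos, len, n) {
  stopifnot(pos >= 0, pos < len)
  cum <- cumsum(window_sizes(len, n))
  sum(cum <= pos) + 1L
}

# merge 0-based half-open intervals given as a 2-column matrix;
# overlapping and book-ended intervals coalesce (same semantics as
# IRanges::reduce on the equivalent closed ranges)
merge_intervals0 <- function(mat) {
  if (is.null(mat) || nrow(mat) == 0) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  }
  n <- nrow(mat)
  if (n == 1) {
    return(matrix(as.integer(mat), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  }
  o <- order(mat[, 1], mat[, 2])
  s <- as.integer(mat[o, 1])
  e <- as.integer(mat[o, 2])
  ce <- cummax(e)
  new_grp <- c(TRUE, s[-1] > ce[-n])  # strict: book-ended intervals merge
  last <- which(c(new_grp[-1], TRUE))
  cbind(start = s[new_grp], end = ce[last])
}

# cumulative covered-bases function of a merged (sorted, disjoint)
# interval set: C(x) = number of covered bases in [0, x).  Vectorised in x.
covered_before <- function(merged, x) {
  if (nrow(merged) == 0) return(numeric(length(x)))
  s <- merged[, 1]; e <- merged[, 2]
  cum <- c(0, cumsum(as.numeric(e - s)))
  idx <- findInterval(x, s)
  partial <- numeric(length(x))
  inside <- idx >= 1
  partial[inside] <- pmax(0, e[idx[inside]] - x[inside])
  cum[idx + 1] - partial
}

# total overlap of each query interval with a merged interval set
overlap_with_merged <- function(queries, merged) {
  covered_before(merged, queries[, 2]) - covered_before(merged, queries[, 1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count1 <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0
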