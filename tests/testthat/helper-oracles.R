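# Independent brute-force oracles and small fixture builders used across
# the suite.  Oracles work per base (or by exhaustive enumeration) and
# share no code with the implementation paths they check.

# ---- per-base interval oracles (0-based half-open, single chromosome) ----

# merge: mark covered bases, read off maximal runs
oracle_merge <- function(mat, genome_size) {
  covered <- logical(genome_size)
  for (i in seq_len(nrow(mat))) {
    if (mat[i, 1] < mat[i, 2]) covered[(mat[i, 1] + 1):mat[i, 2]] <- TRUE
  }
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  cbind(start = starts[r$values], end = ends[r$values])
}

# bedtools-intersect "-f" retention: a peak survives when covered_b bases
# within it amount to >= frac of its length; result is the merged union of
# survivors from both directions
oracle_reproducible <- function(a, b, frac, genome_size) {
  cover <- function(mat) {
    cv <- logical(genome_size)
    for (i in seq_len(nrow(mat))) {
      if (mat[i, 1] < mat[i, 2]) cv[(mat[i, 1] + 1):mat[i, 2]] <- TRUE
    }
    cv
  }
  keep_from <- function(q, scov) {
    ok <- vapply(seq_len(nrow(q)), function(i) {
      len <- q[i, 2] - q[i, 1]
      sum(scov[(q[i, 1] + 1):q[i, 2]]) >= frac * len
    }, NA)
    q[ok, , drop = FALSE]
  }
  kept <- rbind(keep_from(a, cover(b)), keep_from(b, cover(a)))
  if (nrow(kept) == 0) return(kept)
  oracle_merge(kept, genome_size)
}

# per-base mean of a bedGraph-like track over query intervals
oracle_region_mean <- function(intervals, signal, genome_size) {
  val <- rep(NA_real_, genome_size)
  for (i in seq_len(nrow(signal))) {
    val[(signal$start[i] + 1):signal$end[i]] <- signal$value[i]
  }
  in_q <- logical(genome_size)
  for (i in seq_len(nrow(intervals))) {
    in_q[(intervals$start[i] + 1):intervals$end[i]] <- TRUE
  }
  v <- val[in_q]
  if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
}

# per-base window coverage for one single-exon transcript: enumerate
# every spliced base, derive its genomic coordinate by direct arithmetic
# (independent of the package's mapping code), locate its window by
# cumulative window sizes, and check peak membership
oracle_window_row <- function(model, peaks_mat) {
  stopifnot(nrow(model$exons) == 1)
  widths <- function(len, n) {
    base <- len %/% n
    base + as.integer(seq_len(n) <= len %% n)
  }
  sizes <- c(widths(model$len5utr, 10), widths(model$lencds, 20),
             widths(model$len3utr, 20))
  win_of <- rep(seq_len(50), times = sizes)
  total <- model$spliced_length
  gstart <- model$exons[1, 1]
  g <- if (model$strand == "+") gstart + (seq_len(total) - 1L) else
    gstart + (total - seq_len(total))
  covered <- rep(FALSE, total)
  for (i in seq_len(nrow(peaks_mat))) {
    covered <- covered | (g >= peaks_mat[i, 1] & g < peaks_mat[i, 2])
  }
  out <- numeric(50)
  for (w in seq_len(50)) {
    idx <- win_of == w
    out[w] <- if (any(idx)) mean(covered[idx]) else 0
  }
  out
}

# ---- exact-test oracles ----

# two-sided Fisher p by enumeration over all tables with the observed
# marginals, probabilities from factorial ratios (choose), not dhyper
oracle_fisher <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c + d; c1 <- a + c; N <- r1 + r2
  support <- max(0, c1 - r2):min(r1, c1)
  prob <- vapply(support, function(x) {
    choose(r1, x) * choose(r2, c1 - x) / choose(N, c1)
  }, 0)
  p_obs <- prob[support == a]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-7)]))
}

# BH step-up from first principles
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj_sorted <- rev(cummin(rev(p[o] * n / seq_len(n))))
  out <- numeric(n)
  out[o] <- pmin(1, adj_sorted)
  out
}

# ---- fixture builders ----

# random single-exon toy transcript (0-based); returns a TranscriptModel
random_toy_transcript <- function(gene = "G1", genome_size = 10000) {
  len5 <- sample(50:120, 1)
  lencds <- 3 * sample(40:120, 1)
  len3 <- sample(100:250, 1)
  total <- len5 + lencds + len3
  s <- sample.int(genome_size - total, 1)
  strand <- sample(c("+", "-"), 1)
  cds <- if (strand == "+") c(s + len5, s + len5 + lencds) else
    c(s + len3, s + len3 + lencds)
  transcript_model(gene, paste0(gene, ".T1"), "chr1", strand,
                   exons = cbind(s, s + total), cds = rbind(cds))
}

# write a toy GTF from a list of records: list(gene, tx, strand,
# exons = 2-col 0-based matrix, cds = matrix or NULL)
write_toy_gtf <- function(records, path = tempfile(fileext = ".gtf")) {
  lines <- unlist(lapply(records, function(r) {
    fmt <- function(type, m) {
      vapply(seq_len(nrow(m)), function(i) {
        paste("chr1", "toy", type, m[i, 1] + 1, m[i, 2], ".", r$strand, ".",
              sprintf('gene_id "%s"; transcript_id "%s";', r$gene, r$tx),
              sep = "\t")
      }, "")
    }
    c(fmt("exon", r$exons), if (!is.null(r$cds)) fmt("CDS", r$cds))
  }))
  writeLines(lines, path)
  path
}

# PeakSet from a bare interval matrix
peakset_from_mat <- function(mat, chrom = "chr1", fold = 10, fdr = 1e-4) {
  n <- nrow(mat)
  df <- data.frame(chrom = rep(chrom, n), start = as.integer(mat[, 1]),
                   end = as.integer(mat[, 2]),
                   fold_enrichment = rep(fold, n),
                   fdr = rep(fdr, n), sample_id = rep("s1", n),
                   stringsAsFactors = FALSE)
  structure(df, provenance = "s1", class = c("PeakSet", "data.frame"))
}

random_intervals <- function(n, genome_size, max_len = 500) {
  s <- sample.int(genome_size - max_len, n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  cbind(s, pmin(s + len, genome_size))
}
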