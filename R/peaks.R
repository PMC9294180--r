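# m6A peak interval handling: narrowPeak/BED6 I/O, enrichment/FDR
# filtering, replicate reproducibility (bedtools "-f 0.5" semantics),
# merging, region-priority annotation, and per-base signal averaging.
#
# A peak set is a data.frame with columns chrom, start, end (0-based
# half-open), fold_enrichment, fdr, sample_id, carrying a "provenance"
# attribute (character vector of sample ids).

new_peakset <- function(df, provenance) {
  rownames(df) <- NULL
  structure(df, provenance = provenance, class = c("PeakSet", "data.frame"))
}

peakset_columns <- c("chrom", "start", "end", "fold_enrichment", "fdr", "sample_id")

empty_peakset <- function(provenance = character(0)) {
  new_peakset(data.frame(chrom = character(0), start = integer(0),
                         end = integer(0), fold_enrichment = numeric(0),
                         fdr = numeric(0), sample_id = character(0),
                         stringsAsFactors = FALSE), provenance)
}

as_granges_peaks <- function(ps) {
  gr0(ps$chrom, ps$start, ps$end)
}

#' Read m6A peaks from a narrowPeak or BED6 file
#'
#' ENCODE narrowPeak (10 columns) files carry per-peak enrichment and FDR:
#' column 7 (signalValue) is taken as the fold enrichment over input and
#' column 9 (qValue, -log10 scale) is converted to `fdr = 10^(-q)`.
#' BED6 input is treated as pre-filtered: peaks get a `+Inf` fold
#' enrichment sentinel and `fdr = 0` so they survive [filter_peaks()].
#' Coordinates are kept 0-based half-open, as in the files.
#'
#' @param path path to a tab-separated narrowPeak (10 columns) or BED6
#'   (6 columns) file.
#' @param sample_id sample label recorded on every peak; defaults to the
#'   file name without extension.
#' @return A `PeakSet` data.frame.  Records with `start >= end` are
#'   rejected with a warning; a non-numeric score column is a parse error.
#' @export
read_peaks <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("peak file not found: ", path)
  sample_id <- sample_id %||% sub("\\.[^.]*$", "", basename(path))
  if (file.size(path) == 0) return(empty_peakset(sample_id))
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#",
                           quote = "")
  nc <- ncol(raw)
  if (!nc %in% c(6L, 10L)) {
    stop("expected 6 (BED6) or 10 (narrowPeak) columns, found ", nc,
         " in ", path)
  }
  if (!is.numeric(raw[[2]]) || !is.numeric(raw[[3]])) {
    stop("non-numeric start/end in ", path)
  }
  if (nc == 10L) {
    if (!is.numeric(raw[[7]]) || !is.numeric(raw[[9]])) {
      stop("non-numeric signalValue/qValue score column in ", path)
    }
    fold <- as.numeric(raw[[7]])
    fdr <- 10^(-as.numeric(raw[[9]]))
  } else {
    if (!is.numeric(raw[[5]])) stop("non-numeric score column in ", path)
    fold <- rep(Inf, nrow(raw))
    fdr <- rep(0, nrow(raw))
  }
  df <- data.frame(chrom = as.character(raw[[1]]),
                   start = as.integer(raw[[2]]), end = as.integer(raw[[3]]),
                   fold_enrichment = fold, fdr = fdr,
                   sample_id = sample_id,
                   name = as.character(raw[[4]]), stringsAsFactors = FALSE)
  bad <- df$start >= df$end
  if (any(bad)) {
    warning(sum(bad), " record(s) with start >= end rejected in ", path)
    df <- df[!bad, , drop = FALSE]
  }
  new_peakset(df, sample_id)
}

#' Filter peaks on enrichment and FDR
#'
#' Keeps peaks with more than `min_fold` enrichment over input and FDR
#' strictly below `max_fdr` (both comparisons strict, so a peak at exactly
#' two-fold or FDR exactly 0.05 is removed).
#'
#' @param ps a `PeakSet`.
#' @param min_fold minimum fold enrichment (exclusive). Default 2.
#' @param max_fdr maximum FDR (exclusive). Default 0.05.
#' @return Filtered `PeakSet`.
#' @export
filter_peaks <- function(ps, min_fold = 2, max_fdr = 0.05) {
  keep <- ps$fold_enrichment > min_fold & ps$fdr < max_fdr
  new_peakset(as.data.frame(ps)[keep, , drop = FALSE], attr(ps, "provenance"))
}

#' Reproducible peaks between two replicate samples
#'
#' A peak of one replicate is retained when the summed overlap with the
#' other replicate's (merged) peaks covers at least `min_frac` of its own
#' length -- the semantics of `bedtools intersect -f`, applied
#' symmetrically in both directions.  The union of retained peaks is then
#' merged into non-overlapping intervals.
#'
#' @param a,b `PeakSet`s from two replicates of the same condition.
#' @param min_frac minimum fraction of the query peak covered
#'   (inclusive). Default 0.5.
#' @return Merged `PeakSet` of reproducible intervals (enrichment/FDR
#'   metadata is dropped; intervals carry both provenances).
#' @export
reproducible_peaks <- function(a, b, min_frac = 0.5) {
  retained <- function(q, s) {
    if (nrow(q) == 0) return(q[0, , drop = FALSE])
    ov <- numeric(nrow(q))
    s_by_chrom <- split(seq_len(nrow(s)), s$chrom)
    for (chr in unique(q$chrom)) {
      qi <- which(q$chrom == chr)
      si <- s_by_chrom[[chr]]
      if (is.null(si)) next
      merged <- merge_intervals0(cbind(s$start[si], s$end[si]))
      ov[qi] <- overlap_with_merged(cbind(q$start[qi], q$end[qi]), merged)
    }
    q[ov >= min_frac * (q$end - q$start), , drop = FALSE]
  }
  kept <- rbind(as.data.frame(retained(a, b))[peakset_columns],
                as.data.frame(retained(b, a))[peakset_columns])
  prov <- unique(c(attr(a, "provenance"), attr(b, "provenance")))
  merge_peaks(new_peakset(kept, prov))
}

#' Merge overlapping or book-ended peaks
#'
#' Coalesces overlapping and book-ended (end == start) intervals into
#' their union, sorted by (chrom, start); mirrors `bedtools merge`
#' defaults.
#'
#' @param ps a `PeakSet`.
#' @return Merged `PeakSet` (metadata columns collapsed: fold enrichment
#'   `NA`, fdr `NA`, sample id `"merged"`).
#' @export
merge_peaks <- function(ps) {
  prov <- attr(ps, "provenance")
  if (nrow(ps) == 0) return(empty_peakset(prov))
  parts <- lapply(sort(unique(ps$chrom)), function(chr) {
    i <- ps$chrom == chr
    m <- merge_intervals0(cbind(ps$start[i], ps$end[i]))
    data.frame(chrom = chr, start = m[, 1], end = m[, 2],
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, parts)
  df$fold_enrichment <- NA_real_
  df$fdr <- NA_real_
  df$sample_id <- "merged"
  new_peakset(df, prov)
}

#' Annotate peaks by region priority
#'
#' Assigns each peak the highest-priority genic category it overlaps by at
#' least 1 bp, using the priority order fiveUTRs > Promoters > threeUTRs >
#' Exons > Introns; peaks overlapping nothing are Intergenic.  Ties across
#' genes within the winning category go to the smallest gene id.
#'
#' @param ps a `PeakSet` (typically merged).
#' @param regions list of [gene_regions()] results for the filtered genes.
#' @return data.frame with columns chrom, start, end, region, gene_id.
#' @export
annotate_peaks <- function(ps, regions) {
  cats <- c(fiveUTRs = "fiveUTR", Promoters = "promoter",
            threeUTRs = "threeUTR", Exons = "exons", Introns = "introns")
  cat_gr <- lapply(cats, function(field) {
    rows <- lapply(regions, function(r) {
      m <- r[[field]]
      if (is.null(m) || nrow(m) == 0) return(NULL)
      data.frame(chrom = r$chrom, start = m[, 1], end = m[, 2],
                 gene_id = r$gene_id, stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    if (is.null(df)) df <- data.frame(chrom = character(0), start = integer(0),
                                      end = integer(0), gene_id = character(0))
    df
  })
  out <- data.frame(chrom = ps$chrom, start = ps$start, end = ps$end,
                    region = "Intergenic", gene_id = NA_character_,
                    stringsAsFactors = FALSE)
  if (nrow(ps) == 0) return(out)
  pg <- as_granges_peaks(ps)
  unassigned <- rep(TRUE, nrow(ps))
  for (lab in names(cats)) {
    df <- cat_gr[[lab]]
    if (nrow(df) == 0 || !any(unassigned)) next
    rg <- gr0(df$chrom, df$start, df$end)
    hits <- GenomicRanges::findOverlaps(pg, rg)
    if (length(hits) == 0) next
    qh <- S4Vectors::queryHits(hits)
    gene <- df$gene_id[S4Vectors::subjectHits(hits)]
    take <- unassigned[qh]
    if (!any(take)) next
    best <- tapply(gene[take], qh[take], function(g) sort(g)[1])
    idx <- as.integer(names(best))
    out$region[idx] <- lab
    out$gene_id[idx] <- as.character(best)
    unassigned[idx] <- FALSE
  }
  out
}

#' Regional frequency of m6A peaks
#'
#' Proportion of annotated peaks located in the 5'UTR, CDS and 3'UTR.
#' Peaks assigned the generic "Exons" category sit in coding exon
#' sequence not claimed by a UTR and are counted as CDS; promoter,
#' intronic and intergenic peaks are excluded from the denominator.
#'
#' @param annotated data.frame from [annotate_peaks()].
#' @return list with `counts` (named integer) and `proportions` (named
#'   numeric summing to 1) over fiveUTRs / CDS / threeUTRs.
#' @export
region_frequency <- function(annotated) {
  if (nrow(annotated) == 0) stop("no annotated peaks")
  lab <- annotated$region
  lab[lab == "Exons"] <- "CDS"
  lab <- factor(lab, levels = c("fiveUTRs", "CDS", "threeUTRs"))
  counts <- table(lab, useNA = "no")
  counts <- structure(as.integer(counts), names = names(counts))
  if (sum(counts) == 0) stop("no peaks in 5'UTR/CDS/3'UTR categories")
  list(counts = counts, proportions = counts / sum(counts))
}

#' Average per-base signal over regions
#'
#' Arithmetic mean of a per-base track (bedGraph-style intervals) across
#' all bases contained in the query intervals.  Bases not covered by the
#' track are excluded from the denominator; if no base is covered the
#' result is `NA` (undefined, distinct from 0).
#'
#' @param intervals data.frame with chrom, start, end (0-based half-open).
#' @param signal data.frame with chrom, start, end, value.
#' @return single numeric mean, or `NA_real_`.
#' @export
region_mean_signal <- function(intervals, signal) {
  if (nrow(intervals) == 0) return(NA_real_)
  total_w <- 0
  total_v <- 0
  sig_by_chrom <- split(seq_len(nrow(signal)), signal$chrom)
  for (chr in unique(intervals$chrom)) {
    qi <- intervals$chrom == chr
    si <- sig_by_chrom[[chr]]
    if (is.null(si)) next
    # query bases counted once each
    q <- merge_intervals0(cbind(intervals$start[qi], intervals$end[qi]))
    o <- order(signal$start[si])
    for (j in si[o]) {
      w <- overlap_with_merged(cbind(signal$start[j], signal$end[j]), q)
      total_w <- total_w + w
      total_v <- total_v + w * signal$value[j]
    }
  }
  if (total_w == 0) return(NA_real_)
  total_v / total_w
}

#' Write a peak set as BED6
#'
#' @param ps a `PeakSet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(ps, path) {
  df <- data.frame(ps$chrom, ps$start, ps$end,
                   name = sprintf("peak_%d", seq_len(nrow(ps))),
                   score = 0L,
                   strand = ".")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
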