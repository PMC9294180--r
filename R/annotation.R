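# Gene-model handling: parse GTF transcripts, pick one representative
# transcript per gene, apply the metatranscript length filters, and map
# genomic positions into (region, window) metatranscript coordinates.

#' Construct a transcript model
#'
#' A `TranscriptModel` holds one transcript's exon/CDS structure together
#' with the spliced lengths of its 5'UTR, CDS and 3'UTR.  All coordinates
#' are 0-based half-open on the genome; region lengths are spliced
#' (intron-free) nucleotide counts.
#'
#' @param gene_id,transcript_id identifiers.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons 2-column integer matrix (start, end), 0-based half-open,
#'   sorted by start, pairwise non-overlapping.
#' @param cds 2-column integer matrix of coding intervals (may have 0 rows
#'   for non-coding transcripts); each interval must lie within the exons.
#' @return An object of class `TranscriptModel` with fields
#'   `len5utr`, `lencds`, `len3utr` (spliced nt) and `cds_complete`
#'   (`FALSE` when the coding length is not a positive multiple of 3).
#' @export
transcript_model <- function(gene_id, transcript_id, chrom, strand, exons,
                             cds = NULL) {
  stopifnot(strand %in% c("+", "-"))
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  if (any(exons[, 1] >= exons[, 2])) {
    stop("exon with start >= end in transcript ", transcript_id)
  }
  if (nrow(exons) > 1 && any(exons[-1, 1] < exons[-nrow(exons), 2])) {
    stop("overlapping exons in transcript ", transcript_id)
  }
  if (is.null(cds) || length(cds) == 0) {
    cds <- matrix(integer(0), ncol = 2)
  } else {
    cds <- matrix(as.integer(cds), ncol = 2)
    cds <- cds[order(cds[, 1]), , drop = FALSE]
  }
  total <- sum(exons[, 2] - exons[, 1])
  t <- structure(list(
    gene_id = gene_id, transcript_id = transcript_id,
    chrom = chrom, strand = strand, exons = exons, cds = cds,
    spliced_length = total,
    len5utr = 0L, lencds = 0L, len3utr = 0L, cds_complete = NA
  ), class = "TranscriptModel")
  if (nrow(cds) > 0) {
    sp <- genomic_intervals_to_spliced(t, cds)
    if (nrow(sp) == 0 || sum(sp[, 2] - sp[, 1]) != sum(cds[, 2] - cds[, 1])) {
      stop("CDS of transcript ", transcript_id, " not contained in its exons")
    }
    t$len5utr <- as.integer(min(sp[, 1]))
    t$lencds <- as.integer(sum(sp[, 2] - sp[, 1]))
    t$len3utr <- as.integer(total - max(sp[, 2]))
    t$cds_complete <- (t$lencds %% 3L == 0L) && t$lencds > 0L
  }
  t
}

#' @export
print.TranscriptModel <- function(x, ...) {
  cat(sprintf("TranscriptModel %s (gene %s) %s:%s %d exon(s); 5'UTR/CDS/3'UTR = %d/%d/%d nt%s\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand, nrow(x$exons),
              x$len5utr, x$lencds, x$len3utr,
              if (isFALSE(x$cds_complete)) " [incomplete CDS]" else ""))
  invisible(x)
}

# map genomic 0-based half-open intervals (matrix) onto spliced coordinates
# oriented 5'->3'; returns merged 2-col matrix in spliced space
genomic_intervals_to_spliced <- function(t, mat) {
  ex <- t$exons
  off <- c(0L, cumsum(ex[, 2] - ex[, 1]))
  total <- t$spliced_length
  out <- list()
  for (i in seq_len(nrow(mat))) {
    s <- mat[i, 1]; e <- mat[i, 2]
    for (j in seq_len(nrow(ex))) {
      a <- max(s, ex[j, 1]); b <- min(e, ex[j, 2])
      if (a < b) {
        out[[length(out) + 1L]] <- c(off[j] + a - ex[j, 1], off[j] + b - ex[j, 1])
      }
    }
  }
  if (length(out) == 0) {
    return(matrix(integer(0), ncol = 2))
  }
  sp <- do.call(rbind, out)
  if (t$strand == "-") {
    sp <- cbind(total - sp[, 2], total - sp[, 1])
  }
  merge_intervals0(sp)
}

# inverse: spliced (5'->3' oriented) interval [s, e) -> genomic intervals
spliced_interval_to_genomic <- function(t, s, e) {
  total <- t$spliced_length
  stopifnot(s >= 0, e <= total, s < e)
  if (t$strand == "-") {
    tmp <- s; s <- total - e; e <- total - tmp
  }
  ex <- t$exons
  off <- c(0L, cumsum(ex[, 2] - ex[, 1]))
  out <- list()
  for (j in seq_len(nrow(ex))) {
    a <- max(s, off[j]); b <- min(e, off[j + 1])
    if (a < b) {
      out[[length(out) + 1L]] <- c(ex[j, 1] + a - off[j], ex[j, 1] + b - off[j])
    }
  }
  merge_intervals0(do.call(rbind, out))
}

#' Read transcript models from a GTF file
#'
#' Parses a GENCODE-dialect GTF (via [rtracklayer::import]) into one
#' [transcript_model()] per annotated transcript.  GTF's 1-based closed
#' coordinates are converted to the package's 0-based half-open convention.
#' UTR lengths are derived from exon-minus-CDS structure on the correct
#' strand; explicit UTR records are not required.
#'
#' @param path path to a GTF file with `gene_id`/`transcript_id` attributes.
#' @return Named list of `TranscriptModel` (names = transcript ids).
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines(paste(c("chr1", "toy", "exon", 1, 300, ".", "+", ".",
#'   'gene_id "G1"; transcript_id "T1";'), collapse = "\t"), gtf)
#' read_gtf(gtf)
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  if (file.size(path) == 0) return(structure(list(), names = character(0)))
  gr <- rtracklayer::import(path, format = "gtf")
  meta <- S4Vectors::mcols(gr)
  keep <- meta$type %in% c("exon", "CDS")
  gr <- gr[keep]
  meta <- S4Vectors::mcols(gr)
  if (length(gr) == 0) return(structure(list(), names = character(0)))
  if (is.null(meta$transcript_id) || is.null(meta$gene_id)) {
    stop("GTF records lack gene_id/transcript_id attributes: ", path)
  }
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    type = as.character(meta$type),
    gene_id = as.character(meta$gene_id),
    transcript_id = as.character(meta$transcript_id),
    stringsAsFactors = FALSE
  )
  models <- list()
  for (d in split(df, df$transcript_id)) {
    tx <- d$transcript_id[1]
    is_ex <- d$type == "exon"
    if (!any(is_ex)) {
      warning("transcript ", tx, " has CDS but no exons; skipped")
      next
    }
    ex <- d[is_ex, , drop = FALSE]
    cd <- d[!is_ex, , drop = FALSE]
    models[[tx]] <- transcript_model(
      gene_id = ex$gene_id[1], transcript_id = tx,
      chrom = ex$chrom[1], strand = ex$strand[1],
      exons = cbind(ex$start, ex$end),
      cds = if (nrow(cd) > 0) cbind(cd$start, cd$end) else NULL
    )
  }
  models
}

#' Select the longest transcript of each gene
#'
#' Chooses, per gene, the transcript with maximal spliced length; ties are
#' broken by the lexicographically smallest transcript id.
#'
#' @param models list of `TranscriptModel` (e.g. from [read_gtf()]).
#' @return Named list of `TranscriptModel`, one per gene (names = gene ids).
#' @export
select_longest_transcript <- function(models) {
  if (length(models) == 0) stop("empty transcript set")
  genes <- vapply(models, `[[`, "", "gene_id")
  txids <- vapply(models, `[[`, "", "transcript_id")
  lens <- vapply(models, `[[`, 0L, "spliced_length")
  out <- list()
  for (g in sort(unique(genes))) {
    i <- which(genes == g)
    i <- i[order(-lens[i], txids[i])][1]
    out[[g]] <- models[[i]]
  }
  out
}

#' Filter representative transcripts on region lengths
#'
#' Removes genes whose representative transcript has a 5'UTR shorter than
#' `min5`, a 3'UTR shorter than `min3`, or a CDS shorter than `mincds`
#' (spliced nucleotides).  The filter is a strict `<`, so boundary values
#' are retained.
#'
#' @param chosen named list from [select_longest_transcript()].
#' @param min5,min3,mincds minimum spliced lengths in nt.
#' @return Filtered named list of `TranscriptModel`.
#' @export
filter_transcripts <- function(chosen, min5 = 50, min3 = 100, mincds = 100) {
  keep <- vapply(chosen, function(t) {
    t$len5utr >= min5 && t$len3utr >= min3 && t$lencds >= mincds
  }, NA)
  out <- chosen[keep]
  if (length(out) == 0) warning("no transcripts pass the length filters")
  out
}

#' Map a genomic position to metatranscript coordinates
#'
#' Maps a genomic base through the transcript's spliced coordinates
#' (oriented 5' to 3') and reports which metatranscript region it falls in,
#' its fractional position within that region, and its global window index
#' (1-10 = 5'UTR, 11-30 = CDS, 31-50 = 3'UTR).
#'
#' @param t a `TranscriptModel` with a CDS.
#' @param pos 0-based genomic coordinate of a base.
#' @return A list with `region`, `fraction` (in `[0, 1)`) and
#'   `window_index`, or `NULL` for intronic/intergenic positions.
#' @export
genomic_to_meta <- function(t, pos) {
  sp <- genomic_intervals_to_spliced(t, cbind(pos, pos + 1L))
  if (nrow(sp) == 0) return(NULL)
  p <- unname(sp[1, 1])
  stopifnot(t$lencds > 0)
  if (p < t$len5utr) {
    region <- "fiveUTR"; q <- p; len <- t$len5utr
  } else if (p < t$len5utr + t$lencds) {
    region <- "CDS"; q <- p - t$len5utr; len <- t$lencds
  } else {
    region <- "threeUTR"; q <- p - t$len5utr - t$lencds; len <- t$len3utr
  }
  list(region = region,
       fraction = q / len,
       window_index = WINDOW_OFFSET[[region]] +
         window_of(q, len, REGION_WINDOWS[[region]]))
}

#' Map a spliced position back to the genome
#'
#' Inverse of the spliced mapping used by [genomic_to_meta()]: given a
#' 0-based position along the spliced transcript (5' to 3'), returns the
#' 0-based genomic coordinate of that base.
#'
#' @param t a `TranscriptModel`.
#' @param spliced_pos 0-based spliced position in `[0, spliced_length)`.
#' @return A single 0-based genomic coordinate.
#' @export
meta_to_genomic <- function(t, spliced_pos) {
  g <- spliced_interval_to_genomic(t, spliced_pos, spliced_pos + 1L)
  g[1, 1]
}

#' Count annotated transcripts per gene
#'
#' Tally of annotated transcript isoforms per gene, computed before any
#' longest-transcript selection; used as the alternative-splicing variant
#' count.
#'
#' @param models list of `TranscriptModel`.
#' @return Named integer vector (names = gene ids).
#' @export
transcript_counts <- function(models) {
  if (length(models) == 0) return(structure(integer(0), names = character(0)))
  tab <- table(vapply(models, `[[`, "", "gene_id"))
  structure(as.integer(tab), names = names(tab))
}

#' Derive annotation regions for peak assignment
#'
#' Builds the genomic interval sets used by [annotate_peaks()]: 5'UTR,
#' CDS, 3'UTR and exon pieces, introns, a promoter (TSS +/- 3 kb by
#' default), and the stop-codon flank covering `stop_flank` spliced
#' nucleotides on each side of the stop codon (crossing the CDS/3'UTR
#' junction; shorter only when CDS or 3'UTR is shorter than the flank).
#'
#' @param t a `TranscriptModel` with a CDS.
#' @param promoter_width half-width of the promoter around the TSS, bp.
#' @param stop_flank spliced nt retained on each side of the stop codon.
#' @return A list of 2-column interval matrices: `fiveUTR`, `CDS`,
#'   `threeUTR`, `exons`, `introns`, `promoter`, `stop_flank`, plus
#'   `gene_id` and `chrom`.
#' @export
gene_regions <- function(t, promoter_width = 3000, stop_flank = 100) {
  stopifnot(inherits(t, "TranscriptModel"))
  total <- t$spliced_length
  empty <- matrix(integer(0), ncol = 2)
  reg <- list(gene_id = t$gene_id, chrom = t$chrom, strand = t$strand)
  reg$exons <- t$exons
  sp2g <- function(s, e) {
    if (s >= e) empty else spliced_interval_to_genomic(t, s, e)
  }
  reg$fiveUTR <- sp2g(0L, t$len5utr)
  reg$CDS <- sp2g(t$len5utr, t$len5utr + t$lencds)
  reg$threeUTR <- sp2g(t$len5utr + t$lencds, total)
  ex <- t$exons
  if (nrow(ex) > 1) {
    reg$introns <- cbind(ex[-nrow(ex), 2], ex[-1, 1])
  } else {
    reg$introns <- empty
  }
  tss <- if (t$strand == "+") ex[1, 1] else ex[nrow(ex), 2] - 1L
  reg$promoter <- cbind(max(0L, tss - as.integer(promoter_width)),
                        tss + as.integer(promoter_width))
  stop_pos <- t$len5utr + t$lencds  # spliced coord of first base after CDS
  fs <- max(stop_pos - as.integer(stop_flank), t$len5utr)
  fe <- min(stop_pos + as.integer(stop_flank), total)
  reg$stop_flank <- sp2g(fs, fe)
  reg
}
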