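# Metatranscript topology: genes x 50 window density matrix from merged
# peaks, k-means into five clusters, centroid labelling into the five m6A
# topology groups (NMG, 5'MG, 3'MG, CMG, SMG).

#' Build the genes x 50 window density matrix
#'
#' For each filtered gene, the spliced 5'UTR, CDS and 3'UTR are divided
#' into 10, 20 and 20 near-equal windows (remainder bases distributed one
#' per window from the 5' end).  Each cell holds the fraction of the
#' window's spliced bases covered by at least one peak, a per-base density
#' in `[0, 1]`; a gene with no peaks has an all-zero row.
#'
#' @param peaks a merged `PeakSet` (non-overlapping intervals).
#' @param transcripts named list of filtered `TranscriptModel` (one per
#'   gene, from [filter_transcripts()]).
#' @return A `WindowMatrix`: numeric matrix genes x 50 with a
#'   `column_map` attribute (data.frame window, region, within-region
#'   index).
#' @export
build_window_matrix <- function(peaks, transcripts) {
  genes <- names(transcripts)
  m <- matrix(0, nrow = length(genes), ncol = N_WINDOWS,
              dimnames = list(genes, sprintf("w%02d", seq_len(N_WINDOWS))))
  by_chrom <- split(seq_len(nrow(peaks)), peaks$chrom)
  for (g in genes) {
    t <- transcripts[[g]]
    idx <- by_chrom[[t$chrom]]
    if (is.null(idx) || length(idx) == 0) next
    pk <- cbind(peaks$start[idx], peaks$end[idx])
    # restrict to the transcript span before spliced mapping
    span <- range(t$exons)
    pk <- pk[pk[, 2] > span[1] & pk[, 1] < span[2], , drop = FALSE]
    if (nrow(pk) == 0) next
    cov <- genomic_intervals_to_spliced(t, pk)
    if (nrow(cov) == 0) next
    # spliced breakpoints of all 50 windows, then window coverage via the
    # cumulative-covered-bases function evaluated at the breaks
    brk <- c(window_breaks(t$len5utr, 10L),
             window_breaks(t$lencds, 20L)[-1] + t$len5utr,
             window_breaks(t$len3utr, 20L)[-1] + t$len5utr + t$lencds)
    cum_cov <- colSums(outer(cov[, 2], brk, pmin) -
                         outer(cov[, 1], brk, pmin))
    covered <- diff(cum_cov)
    size <- diff(brk)
    m[g, size > 0] <- covered[size > 0] / size[size > 0]
  }
  attr(m, "column_map") <- data.frame(
    window = seq_len(N_WINDOWS),
    region = rep(names(REGION_WINDOWS), REGION_WINDOWS),
    index = unlist(lapply(REGION_WINDOWS, seq_len), use.names = FALSE)
  )
  class(m) <- c("WindowMatrix", class(m))
  m
}

#' k-means clustering of window profiles
#'
#' Euclidean k-means on the window matrix: best of `n_init` kmeans++
#' seedings (squared-distance-weighted sampling of initial centres, which
#' reliably seeds every well-separated group) by within-cluster sum of
#' squares.  Rows are canonicalised into lexicographic order before
#' seeding the RNG, so the result is deterministic given `seed` and
#' invariant to gene order.  Each gene's final cluster is its nearest
#' centroid, ties broken towards the smallest cluster id.
#'
#' @param m `WindowMatrix` (or plain numeric matrix with >= k distinct
#'   rows).
#' @param k number of clusters (default 5).
#' @param seed RNG seed.
#' @param n_init number of random starts.
#' @param iter_max maximum iterations per start.
#' @return list with `cluster` (named integer), `centroids` (k x 50),
#'   `inertia` (total within-cluster sum of squares), `seed`.
#' @export
kmeans_cluster <- function(m, k = 5, seed = 42, n_init = 10, iter_max = 300) {
  vals <- unclass(m)
  attr(vals, "column_map") <- NULL
  if (nrow(unique(vals)) < k) {
    stop("fewer than k = ", k, " distinct rows; cannot cluster")
  }
  ord <- do.call(order, c(as.data.frame(vals), list(rownames(vals))))
  canon <- vals[ord, , drop = FALSE]
  km <- local({
    set.seed(seed)
    best <- NULL
    inits <- lapply(seq_len(n_init), function(i) kmeanspp_centres(canon, k))
    if (k == 5) {
      # canonical topology archetypes: the five groups are defined by
      # density concentrated in one meta-region (or none), so one start
      # probes exactly that configuration, scaled to the data
      scale <- mean(canon[canon > 0])
      if (!is.finite(scale) || scale <= 0) scale <- 0.5
      arch <- rbind(rep(0, N_WINDOWS),
                    scale * (seq_len(N_WINDOWS) %in% 1:10),
                    scale * (seq_len(N_WINDOWS) %in% 11:30),
                    scale * (seq_len(N_WINDOWS) %in% 28:32),
                    scale * (seq_len(N_WINDOWS) %in% 31:50))
      inits <- c(list(arch), inits)
    }
    for (centres in inits) {
      fit <- suppressWarnings(stats::kmeans(canon, centers = centres,
                                            iter.max = iter_max))
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    best
  })
  cent <- km$centers
  d2 <- outer(rowSums(vals^2), rep(1, k)) - 2 * vals %*% t(cent) +
    outer(rep(1, nrow(vals)), rowSums(cent^2))
  cl <- apply(d2, 1, which.min)  # which.min takes the smallest index on ties
  names(cl) <- rownames(vals)
  inertia <- sum(d2[cbind(seq_len(nrow(vals)), cl)])
  list(cluster = cl, centroids = cent, inertia = inertia, seed = seed)
}

# kmeans++ seeding: first centre uniform, each further centre sampled
# with probability proportional to squared distance from the nearest
# centre chosen so far; identical rows can never be re-picked
kmeanspp_centres <- function(x, k) {
  n <- nrow(x)
  centres <- matrix(0, nrow = k, ncol = ncol(x))
  i <- sample.int(n, 1)
  centres[1, ] <- x[i, ]
  d2 <- rowSums(sweep(x, 2, centres[1, ])^2)
  for (j in seq_len(k - 1)) {
    if (all(d2 <= 0)) {
      i <- sample.int(n, 1)  # degenerate: all points coincide
    } else {
      i <- sample.int(n, 1, prob = d2)
    }
    centres[j + 1, ] <- x[i, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centres[j + 1, ])^2))
  }
  centres
}

#' Label k-means centroids with topology group names
#'
#' The centroid with the smallest overall mean density is NMG (it must be
#' below half the second-smallest mean, otherwise no cluster is clearly
#' unmethylated and an error asks for a different seed or a k
#' diagnostic).  The remaining four centroids are labelled by the
#' meta-region with maximal mean density: 5'UTR = windows 1-10, CDS body =
#' 11-27, stop-codon flank = 28-32 (SMG), 3'UTR body = 33-50.  The
#' labelling must be bijective.
#'
#' @param centroids k x 50 numeric matrix (k = 5).
#' @return named character vector: cluster id -> group label.
#' @export
label_clusters <- function(centroids) {
  stopifnot(nrow(centroids) == 5, ncol(centroids) == N_WINDOWS)
  mu <- rowMeans(centroids)
  o <- order(mu)
  if (!(mu[o[1]] < 0.5 * mu[o[2]])) {
    stop("no unambiguous NMG centroid (smallest mean ", signif(mu[o[1]], 3),
         " not < 50% of second ", signif(mu[o[2]], 3),
         "); try a different seed or inspect a k diagnostic")
  }
  labels <- rep(NA_character_, 5)
  labels[o[1]] <- "NMG"
  region_label <- c(fiveUTR = "5MG", cds_body = "CMG",
                    stop_flank = "SMG", threeUTR_body = "3MG")
  for (i in o[-1]) {
    region_means <- vapply(LABEL_COLS, function(cols) {
      mean(centroids[i, cols])
    }, 0)
    labels[i] <- region_label[[names(which.max(region_means))]]
  }
  if (anyDuplicated(labels)) {
    stop("centroid labelling is not bijective (",
         paste(labels, collapse = ", "),
         "); try a different seed or inspect a k diagnostic")
  }
  names(labels) <- rownames(centroids) %||% as.character(seq_len(5))
  labels
}

#' Classify genes into the five m6A topology groups
#'
#' Pipeline composition: window matrix from merged peaks, k-means into
#' five clusters, centroid labelling.  If more than 99% of genes have
#' all-zero profiles the k-means step degenerates and is bypassed: all
#' genes are NMG.
#'
#' @param peaks merged `PeakSet`.
#' @param transcripts filtered named list of `TranscriptModel`.
#' @param seed RNG seed (recorded in the result).
#' @param k,n_init passed to [kmeans_cluster()].
#' @return A `TopologyAssignment`: list with `assignment` (named
#'   character, gene -> group), `centroids` (rownames = group labels, or
#'   `NULL` when bypassed), `distance` (per-gene Euclidean distance to its
#'   centroid), `seed`, `inertia`.
#' @export
classify <- function(peaks, transcripts, seed = 42, k = 5, n_init = 10) {
  m <- build_window_matrix(peaks, transcripts)
  zero_rows <- rowSums(unclass(m)) == 0
  if (mean(zero_rows) > 0.99) {
    assignment <- structure(rep("NMG", nrow(m)), names = rownames(m))
    return(structure(list(assignment = assignment, centroids = NULL,
                          distance = structure(rep(0, nrow(m)),
                                               names = rownames(m)),
                          seed = seed, inertia = 0,
                          window_matrix = m),
                     class = "TopologyAssignment"))
  }
  km <- kmeans_cluster(m, k = k, seed = seed, n_init = n_init)
  labels <- label_clusters(km$centroids)
  assignment <- labels[km$cluster]
  names(assignment) <- names(km$cluster)
  cent <- km$centroids
  rownames(cent) <- labels
  cent <- cent[GROUPS, , drop = FALSE]
  dist <- sqrt(rowSums((unclass(m) - km$centroids[km$cluster, , drop = FALSE])^2))
  names(dist) <- names(km$cluster)
  structure(list(assignment = assignment, centroids = cent,
                 distance = dist, seed = seed, inertia = km$inertia,
                 window_matrix = m),
            class = "TopologyAssignment")
}

#' @export
print.TopologyAssignment <- function(x, ...) {
  tab <- table(factor(x$assignment, levels = GROUPS))
  cat("TopologyAssignment over", length(x$assignment), "genes (seed",
      x$seed, "):\n")
  print(tab)
  invisible(x)
}

#' Within-cluster variance diagnostic across k
#'
#' Classification always uses k = 5; this diagnostic reports total
#' within-cluster sum of squares for a range of k to support that choice
#' on a given dataset.
#'
#' @param m `WindowMatrix`.
#' @param ks integer vector of cluster counts to scan.
#' @param seed,n_init as in [kmeans_cluster()].
#' @return data.frame with `k` and `inertia`.
#' @export
kmeans_diagnostic <- function(m, ks = 2:8, seed = 42, n_init = 5) {
  data.frame(k = ks, inertia = vapply(ks, function(k) {
    kmeans_cluster(m, k = k, seed = seed, n_init = n_init)$inertia
  }, 0))
}

#' Metagene density profile plot
#'
#' Plots per-group mean window density (the centroids of a
#' `TopologyAssignment`) along the 50-window metatranscript, with region
#' boundaries at windows 10/11 and 30/31.
#'
#' @param assignment a `TopologyAssignment` with centroids.
#' @param ... passed to [graphics::matplot()].
#' @return invisibly, the centroid matrix plotted.
#' @export
plot_metagene <- function(assignment, ...) {
  cent <- assignment$centroids
  if (is.null(cent)) stop("assignment has no centroids (degenerate all-NMG)")
  graphics::matplot(t(cent), type = "l", lty = 1, lwd = 2,
                    xlab = "metatranscript window (5'UTR | CDS | 3'UTR)",
                    ylab = "mean peak density", ...)
  graphics::abline(v = c(10.5, 30.5), lty = 3)
  graphics::legend("topright", legend = rownames(cent), lty = 1, lwd = 2,
                   col = seq_len(nrow(cent)), bty = "n")
  invisible(cent)
}
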