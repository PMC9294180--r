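# Topological transitions between two stages: 5x5 cross-tabulation,
# overlap ratios, transition ratios, and the derived transition gene sets
# (adult-loss 5'MGs, adult-gain SMGs).

assignment_vector <- function(x) {
  if (inherits(x, "TopologyAssignment")) x <- x$assignment
  if (is.factor(x)) x <- structure(as.character(x), names = names(x))
  stopifnot(is.character(x), !is.null(names(x)), all(x %in% GROUPS))
  x
}

#' Cross-tabulate topology groups between two stages
#'
#' 5x5 contingency table of group labels over the genes shared by the two
#' assignments (rows = stage 1, columns = stage 2); genes unique to one
#' stage are reported separately.
#'
#' @param a,b `TopologyAssignment`s (or named character vectors of group
#'   labels) for stage 1 and stage 2.
#' @return A `TransitionTable`: list with `counts` (5x5 integer matrix),
#'   `pairs` (long data.frame gene/stage1/stage2, alluvial-ready),
#'   `shared_genes`, `only_stage1`, `only_stage2`.
#' @export
cross_tab <- function(a, b) {
  a <- assignment_vector(a)
  b <- assignment_vector(b)
  shared <- intersect(names(a), names(b))
  if (length(shared) == 0) stop("no genes shared between the two stages")
  f1 <- factor(a[shared], levels = GROUPS)
  f2 <- factor(b[shared], levels = GROUPS)
  counts <- table(stage1 = f1, stage2 = f2)
  counts <- matrix(as.integer(counts), nrow = 5,
                   dimnames = list(stage1 = GROUPS, stage2 = GROUPS))
  structure(list(
    counts = counts,
    pairs = data.frame(gene = shared, stage1 = as.character(f1),
                       stage2 = as.character(f2), stringsAsFactors = FALSE),
    shared_genes = shared,
    only_stage1 = setdiff(names(a), shared),
    only_stage2 = setdiff(names(b), shared)
  ), class = "TransitionTable")
}

#' Overlap ratio of topology groups across stages
#'
#' For each group, the proportion of genes keeping the same label across
#' the two stages, relative to the group's size in the reference stage:
#' diagonal count divided by the row (stage 1) or column (stage 2)
#' marginal.  Groups with a zero marginal are undefined (`NA`).
#'
#' @param t a `TransitionTable`.
#' @param group group label(s); default all five.
#' @param reference `"stage1"`, `"stage2"`, or both (default).
#' @return data.frame with `group`, `reference`, `ratio`.
#' @export
overlap_ratio <- function(t, group = GROUPS,
                          reference = c("stage1", "stage2")) {
  reference <- match.arg(reference, several.ok = TRUE)
  stopifnot(all(group %in% GROUPS))
  out <- expand.grid(group = group, reference = reference,
                     stringsAsFactors = FALSE)
  out$ratio <- mapply(function(g, ref) {
    marg <- if (ref == "stage1") sum(t$counts[g, ]) else sum(t$counts[, g])
    if (marg == 0) NA_real_ else t$counts[g, g] / marg
  }, out$group, out$reference)
  out
}

#' Transition ratios from stage 1 to stage 2
#'
#' Row-normalised transition counts, using stage 1 (e.g. fetal) as the
#' reference: cell (i, j) is the proportion of stage-1 group-i genes found
#' in stage-2 group j.  Rows with a zero marginal are all-`NA`.
#'
#' @param t a `TransitionTable`.
#' @return 5x5 numeric matrix; defined rows sum to 1.
#' @export
transition_ratio <- function(t) {
  marg <- rowSums(t$counts)
  out <- t$counts / marg
  out[marg == 0, ] <- NA_real_
  out
}

#' Derived transition gene sets
#'
#' The four gene sets characterising the dominant fetal-to-adult
#' topology changes:
#' * `adult_loss_5MG`: stage-1 5'MG and stage-2 NMG (m6A lost from the
#'   5'UTR);
#' * `adult_retain_5MG`: 5'MG in both stages;
#' * `adult_gain_SMG`: stage-2 SMG that was not SMG in stage 1;
#' * `adult_retain_SMG`: SMG in both stages.
#'
#' @param t a `TransitionTable`.
#' @return list of four character vectors of gene ids.
#' @export
transition_sets <- function(t) {
  p <- t$pairs
  list(
    adult_loss_5MG = p$gene[p$stage1 == "5MG" & p$stage2 == "NMG"],
    adult_retain_5MG = p$gene[p$stage1 == "5MG" & p$stage2 == "5MG"],
    adult_gain_SMG = p$gene[p$stage2 == "SMG" & p$stage1 != "SMG"],
    adult_retain_SMG = p$gene[p$stage1 == "SMG" & p$stage2 == "SMG"]
  )
}

#' @export
print.TransitionTable <- function(x, ...) {
  cat("TransitionTable over", length(x$shared_genes), "shared genes\n")
  print(x$counts)
  invisible(x)
}
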