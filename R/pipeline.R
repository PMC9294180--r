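# End-to-end pipeline over a synthetic (or synthetic-format) dataset:
# annotation -> peak filtering/reproducibility/merging -> per-stage
# topology classification -> transition analysis -> quantification ->
# tissue-specificity, with every table written as TSV.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Stage peaks: filter, intersect replicates, merge
#'
#' Applies the peak-confidence pipeline for one condition: per-replicate
#' enrichment/FDR filtering, replicate reproducibility at `min_frac`
#' overlap, and merging.  More than two replicates are reduced by
#' sequential pairwise intersection in input order (with a warning), as
#' the design assumes two replicates per condition.
#'
#' @param paths character vector of narrowPeak/BED6 paths (replicates).
#' @param min_fold,max_fdr,min_frac thresholds (see [filter_peaks()] and
#'   [reproducible_peaks()]).
#' @return merged `PeakSet` of confident peaks.
#' @export
confident_peaks <- function(paths, min_fold = 2, max_fdr = 0.05,
                            min_frac = 0.5) {
  sets <- lapply(paths, read_peaks)
  sets <- lapply(sets, filter_peaks, min_fold = min_fold, max_fdr = max_fdr)
  if (length(sets) == 1) return(merge_peaks(sets[[1]]))
  if (length(sets) > 2) {
    warning("more than two replicates; reducing by sequential pairwise ",
            "intersection in input order")
  }
  Reduce(function(a, b) reproducible_peaks(a, b, min_frac = min_frac), sets)
}

#' Run the full m6A topology pipeline
#'
#' Generates a synthetic dataset from `config`, then runs every stage of
#' the analysis and writes all result tables under `out_dir`:
#' filtered gene list, per-stage merged peaks (BED), window matrices,
#' topology assignments and centroids, 5x5 transition counts, overlap and
#' transition ratios, transition gene sets, region frequencies with the
#' fetal-vs-adult 5'UTR z-test, TPM/TMM/m6A levels, differential
#' expression calls, m6A-level/expression correlations, and tau scores.
#' All outputs are plain TSV (or BED) and byte-identical across runs with
#' the same seed.
#'
#' @param config a `SyntheticConfig`; its `seed` drives both data
#'   generation and clustering.
#' @param out_dir output directory.
#' @return list with the computed objects (`assignments`, `transition`,
#'   `ratios`, `sets`, `levels`, `de`, `tau`, ...) and `files`, the named
#'   vector of written paths.
#' @export
run_all <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ds <- generate_dataset(config, file.path(out_dir, "data"))
  files <- c()

  models <- read_gtf(ds$gtf)
  chosen <- select_longest_transcript(models)
  kept <- filter_transcripts(chosen)
  files["genes"] <- write_tsv(data.frame(
    gene_id = names(kept),
    len5utr = vapply(kept, `[[`, 0L, "len5utr"),
    lencds = vapply(kept, `[[`, 0L, "lencds"),
    len3utr = vapply(kept, `[[`, 0L, "len3utr")
  ), file.path(out_dir, "filtered_genes.tsv"))

  stages <- names(ds$peaks)
  assignments <- list()
  freqs <- list()
  # transcript-region annotation (no promoter category): region
  # frequencies describe where m6A sits on the mRNA, so the genomic
  # promoter window must not shadow CDS/3'UTR assignments
  regions <- lapply(kept, gene_regions, promoter_width = 0)
  for (st in stages) {
    pk <- confident_peaks(ds$peaks[[st]])
    files[paste0("peaks_", st)] <- write_peaks_bed(
      pk, file.path(out_dir, sprintf("peaks_%s_merged.bed", st)))
    asn <- classify(pk, kept, seed = config$seed)
    assignments[[st]] <- asn
    files[paste0("assignment_", st)] <- write_tsv(data.frame(
      gene_id = names(asn$assignment), group = unname(asn$assignment),
      distance = unname(asn$distance)
    ), file.path(out_dir, sprintf("assignment_%s.tsv", st)))
    if (!is.null(asn$centroids)) {
      files[paste0("centroids_", st)] <- write_tsv(
        data.frame(group = rownames(asn$centroids), asn$centroids),
        file.path(out_dir, sprintf("centroids_%s.tsv", st)))
    }
    ann <- annotate_peaks(pk, regions)
    freqs[[st]] <- region_frequency(ann)
  }

  ztest <- two_proportion_ztest(
    freqs[[1]]$counts["fiveUTRs"], sum(freqs[[1]]$counts),
    freqs[[2]]$counts["fiveUTRs"], sum(freqs[[2]]$counts))
  files["region_frequency"] <- write_tsv(data.frame(
    stage = rep(stages, each = 3),
    region = rep(names(freqs[[1]]$counts), 2),
    count = unname(c(freqs[[1]]$counts, freqs[[2]]$counts)),
    proportion = unname(c(freqs[[1]]$proportions, freqs[[2]]$proportions)),
    fiveutr_z = ztest$statistic, fiveutr_p = ztest$pvalue
  ), file.path(out_dir, "region_frequency.tsv"))

  tt <- cross_tab(assignments[[1]], assignments[[2]])
  files["transition_counts"] <- write_tsv(
    data.frame(stage1 = rownames(tt$counts), tt$counts),
    file.path(out_dir, "transition_counts.tsv"))
  files["transition_long"] <- write_tsv(
    tt$pairs, file.path(out_dir, "transition_long.tsv"))
  ratios <- transition_ratio(tt)
  files["transition_ratio"] <- write_tsv(
    data.frame(stage1 = rownames(ratios), ratios),
    file.path(out_dir, "transition_ratio.tsv"))
  ov <- overlap_ratio(tt)
  files["overlap_ratio"] <- write_tsv(
    ov, file.path(out_dir, "overlap_ratio.tsv"))
  sets <- transition_sets(tt)
  for (nm in names(sets)) {
    files[nm] <- file.path(out_dir, paste0(nm, ".txt"))
    writeLines(sort(sets[[nm]]), files[nm])
  }

  # quantification per stage: TPM, m6A level; DE between stages on pooled
  # input counts with TMM-scaled libraries
  levels <- list()
  expr <- list()
  pooled <- list()
  for (st in stages) {
    ct <- read_count_table(ds$counts[[st]], ds$samples)
    roles <- ct$samples$role[match(colnames(ct$counts), ct$samples$sample)]
    tp <- tpm(ct$counts, ct$lengths)
    ip <- rowMeans(tp[, roles == "IP", drop = FALSE])
    inp <- rowMeans(tp[, roles == "input", drop = FALSE])
    expr[[st]] <- inp
    levels[[st]] <- m6a_level(ip, inp)
    files[paste0("m6a_level_", st)] <- write_tsv(
      levels[[st]], file.path(out_dir, sprintf("m6a_level_%s.tsv", st)))
    pooled[[st]] <- rowSums(ct$counts[, roles == "input", drop = FALSE])
  }
  pooled_mat <- cbind(pooled[[1]], pooled[[2]])
  tmm <- tmm_factors(pooled_mat)
  de <- differential_genes(cbind(
    data.frame(gene_id = rownames(pooled_mat)),
    rate_ratio_test(pooled_mat[, 2], pooled_mat[, 1],
                    scaleA = 1 / tmm[2], scaleB = 1 / tmm[1])
  ))
  files["de"] <- write_tsv(de, file.path(out_dir, "de_genes.tsv"))

  # m6A level vs expression correlation within methylated genes, per stage
  cors <- lapply(stages, function(st) {
    meth <- names(assignments[[st]]$assignment)[
      assignments[[st]]$assignment != "NMG"]
    lv <- levels[[st]]
    sel <- lv$gene_id %in% meth & lv$flag == "ok" & lv$level > 0
    r <- pearson_correlation(log2(lv$level[sel]),
                             log2(expr[[st]][lv$gene_id[sel]]))
    data.frame(stage = st, r = r$statistic, pvalue = r$pvalue, n = r$n)
  })
  files["correlation"] <- write_tsv(do.call(rbind, cors),
                                    file.path(out_dir, "m6a_expr_correlation.tsv"))

  panel <- utils::read.table(ds$tissue_panel, header = TRUE, sep = "\t",
                             row.names = 1, check.names = FALSE)
  tau_scores <- tau(as.matrix(panel))
  files["tau"] <- write_tsv(
    data.frame(gene_id = names(tau_scores), tau = unname(tau_scores)),
    file.path(out_dir, "tau.tsv"))

  list(dataset = ds, genes = kept, assignments = assignments,
       transition = tt, ratios = ratios, overlap = ov, sets = sets,
       region_frequency = freqs, fiveutr_ztest = ztest,
       levels = levels, expression = expr, de = de, tmm = tmm,
       tau = tau_scores, files = files)
}
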