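# Seed-reproducible synthetic MeRIP-seq dataset with planted truth:
# annotation (GTF), two-stage replicated peak files (narrowPeak), IP/input
# count tables, a multi-tissue expression panel, and a truth table giving
# every gene's planted topology class in both stages.

default_transition_matrix <- function() {
  tm <- matrix(0.1, nrow = 5, ncol = 5, dimnames = list(GROUPS, GROUPS))
  diag(tm) <- 0.6
  # the 5'MG row carries the dominant developmental transition:
  # half of the fetal 5'MGs lose their 5'UTR methylation entirely
  tm["5MG", ] <- c(NMG = 0.5, `5MG` = 0.3, `3MG` = 0.1, CMG = 0.05, SMG = 0.05)
  tm
}

#' Configuration for the synthetic dataset generator
#'
#' Defines the study conditions the generator emulates: per-gene region
#' lengths honouring the metatranscript length filters, five planted
#' topology classes, a row-stochastic 5x5 stage-transition matrix,
#' negative-binomial IP/input counts with log-normal expression, a planted
#' negative correlation between m6A level and expression, and a
#' multi-tissue panel with known specificity.
#'
#' @param n_genes number of genes.
#' @param class_probs named probabilities over the five groups (sum 1).
#' @param transition_matrix 5x5 row-stochastic matrix (stage-1 groups in
#'   rows); default: diagonal 0.6 with the 5'MG row dominated by the
#'   5'MG -> NMG transition (0.5).
#' @param len5_range,lencds_range,len3_range spliced region length ranges
#'   in nt (CDS lengths are rounded to multiples of 3).
#' @param peak_len_range peak length range in nt; must fit inside every
#'   feasible target region.
#' @param coverage_target fraction of a methylated gene's target region
#'   covered by peaks in expectation; sets the number of peaks placed per
#'   gene (topology groups show enrichment across much of the region).
#' @param n_replicates peak/count replicates per stage (2, as in paired
#'   MeRIP designs).
#' @param expr_meanlog,expr_sdlog log-normal expression parameters
#'   (natural-log scale).
#' @param m6a_effect multiplicative IP enrichment for methylated genes.
#' @param m6a_expr_rho target correlation between log2 m6A level and log2
#'   expression among methylated genes (negative).
#' @param m6a_level_sdlog2 spread of planted log2 m6A levels.
#' @param nb_dispersion negative-binomial dispersion (constant across
#'   genes).
#' @param n_tissues tissues in the expression panel.
#' @param frac_filter_fail fraction of genes violating the 5'UTR length
#'   filter (these receive no peaks and exercise the filtering path).
#' @param jitter_frac replicate peak-boundary jitter as a fraction of
#'   peak length; at the default 0.2 the two replicates always retain at
#'   least 50% reciprocal overlap.  Set 0 for noise-free data.
#' @param decoy_rate per-gene, per-stage probability of one additional
#'   sub-threshold peak (fold <= 2 or FDR >= 0.05) that [filter_peaks()]
#'   must remove. Default 0.
#' @param de_frac,de_lfc fraction of genes with planted differential
#'   expression between stages, and the planted |log2FC|.
#' @param spec_frac fraction of tissue-specific genes in the panel.
#' @param multi_exon give each gene 2-3 exons instead of one, to exercise
#'   spliced-coordinate mapping.
#' @param seed RNG seed; the whole dataset is deterministic given it.
#' @return A `SyntheticConfig` list.
#' @export
synthetic_config <- function(n_genes = 2000,
                             class_probs = c(NMG = 0.2, `5MG` = 0.2,
                                             `3MG` = 0.2, CMG = 0.2,
                                             SMG = 0.2),
                             transition_matrix = default_transition_matrix(),
                             len5_range = c(150, 300),
                             lencds_range = c(300, 1500),
                             len3_range = c(250, 800),
                             peak_len_range = c(100, 150),
                             coverage_target = 0.7,
                             n_replicates = 2,
                             expr_meanlog = 5, expr_sdlog = 1,
                             m6a_effect = 4, m6a_expr_rho = -0.5,
                             m6a_level_sdlog2 = 1.5,
                             nb_dispersion = 0.05,
                             n_tissues = 12,
                             frac_filter_fail = 0.05,
                             jitter_frac = 0.2,
                             decoy_rate = 0,
                             de_frac = 0.1, de_lfc = 2,
                             spec_frac = 0.2,
                             multi_exon = FALSE,
                             seed = 1) {
  stopifnot(length(class_probs) == 5,
            abs(sum(class_probs) - 1) < 1e-8,
            all(dim(transition_matrix) == c(5, 5)),
            all(abs(rowSums(transition_matrix) - 1) < 1e-8),
            all(class_probs >= 0), all(transition_matrix >= 0))
  names(class_probs) <- GROUPS
  dimnames(transition_matrix) <- list(GROUPS, GROUPS)
  pl <- peak_len_range[2]
  if (pl > len5_range[1]) {
    stop("peak_len_range: maximum peak length exceeds the minimum 5'UTR ",
         "length; 5'MG peak placement would be infeasible")
  }
  if (pl > lencds_range[1] - 100) {
    stop("peak_len_range: maximum peak length exceeds the CDS interior ",
         "(lencds_range minimum - 100 nt)")
  }
  if (pl > len3_range[1] - 100) {
    stop("peak_len_range: maximum peak length exceeds the 3'UTR interior ",
         "(len3_range minimum - 100 nt)")
  }
  structure(as.list(environment()), class = "SyntheticConfig")
}

# spliced peak intervals for one gene given its class; NULL for NMG.
# A topology group's enrichment spans its region, so the region is tiled
# with peaks: the target window is split into strata of roughly one mean
# peak length each and one peak is placed inside each stratum at a random
# offset.  This gives every gene of a class a coherent dense profile over
# its region while keeping individual peak boundaries realistic.  SMG
# tiles the +/-100 nt stop-codon window.
place_peaks <- function(class, len5, lencds, len3, peak_range, coverage) {
  total <- len5 + lencds + len3
  stop_pos <- len5 + lencds
  window <- switch(class,
    NMG = return(NULL),
    `5MG` = c(0L, len5),
    CMG = c(len5, stop_pos - 100L),
    `3MG` = c(stop_pos + 100L, total),
    SMG = {
      # peak centres lie within +/-100 nt of the stop codon, so the
      # tiled window extends half a peak length beyond on each side
      half <- as.integer(mean(peak_range)) %/% 2L
      c(max(0L, stop_pos - 100L - half),
        min(total, stop_pos + 100L + half))
    })
  avail <- window[2] - window[1]
  mean_pl <- mean(peak_range)
  n_pk <- max(1L, as.integer(ceiling(coverage * avail / mean_pl)))
  brk <- window[1] + as.integer(round(seq(0, avail, length.out = n_pk + 1)))
  out <- matrix(0L, nrow = n_pk, ncol = 2)
  for (i in seq_len(n_pk)) {
    pl <- sample(seq(peak_range[1], peak_range[2]), 1L)
    lo <- brk[i]
    hi <- min(brk[i + 1], window[2] - pl)
    hi <- max(hi, lo)
    s <- if (hi > lo) lo + sample.int(hi - lo + 1L, 1L) - 1L else lo
    s <- max(window[1], min(s, window[2] - pl))
    out[i, ] <- c(s, s + pl)
  }
  out
}

gtf_line <- function(chrom, feature, start0, end0, strand, gene, tx = NULL) {
  attrs <- sprintf('gene_id "%s";', gene)
  if (!is.null(tx)) attrs <- paste(attrs, sprintf('transcript_id "%s";', tx))
  paste(chrom, "synthetic", feature, start0 + 1L, end0, ".", strand, ".",
        attrs, sep = "\t")
}

#' Generate a synthetic two-stage MeRIP-seq dataset
#'
#' Writes, under `out_dir`: `annotation.gtf`;
#' `peaks_<stage>_rep<i>.narrowPeak` for stages fetal/adult;
#' `counts_<stage>.tsv` (gene_id, length, input and IP replicates) with a
#' shared `samples.tsv` sheet; `tissue_panel.tsv`; and `truth.tsv` with
#' the planted per-gene classes and parameters.  Deterministic given
#' `config$seed`: the same seed yields byte-identical files.
#'
#' Peak placement by planted class: 5'MG inside the 5'UTR; CMG inside the
#' CDS excluding its last 100 nt; SMG centred within +/-30 nt of the stop
#' codon; 3'MG inside the 3'UTR excluding its first 100 nt; NMG none.
#' Each replicate's boundaries are jittered (see
#' [synthetic_config()]).  Genes violating the length filters receive no
#' peaks.
#'
#' @param config a `SyntheticConfig`.
#' @param out_dir output directory (created if needed).
#' @return A `SyntheticDataset` list: file paths (`gtf`, `peaks` nested by
#'   stage, `counts`, `samples`, `tissue_panel`, `truth_path`), the
#'   `truth` data.frame, and the `config`.
#' @export
generate_dataset <- function(config, out_dir) {
  stopifnot(inherits(config, "SyntheticConfig"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  n <- config$n_genes
  stages <- c("fetal", "adult")

  genes <- if (n > 0) sprintf("G%05d", seq_len(n)) else character(0)
  fail5 <- stats::runif(n) < config$frac_filter_fail
  len5 <- ifelse(fail5,
                 sample(10:49, n, replace = TRUE),
                 sample(seq(config$len5_range[1], config$len5_range[2]),
                        n, replace = TRUE))
  cds3 <- seq(ceiling(config$lencds_range[1] / 3),
              floor(config$lencds_range[2] / 3))
  lencds <- 3L * sample(cds3, n, replace = TRUE)
  len3 <- sample(seq(config$len3_range[1], config$len3_range[2]),
                 n, replace = TRUE)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  total <- len5 + lencds + len3

  class1 <- if (n > 0) sample(GROUPS, n, replace = TRUE,
                              prob = config$class_probs) else character(0)
  class2 <- vapply(class1, function(c1) {
    sample(GROUPS, 1, prob = config$transition_matrix[c1, ])
  }, "", USE.NAMES = FALSE)

  # gene bodies laid head-to-tail on one chromosome with 10 kb gaps
  gtf <- character(0)
  models <- vector("list", n)
  pos <- 10000L
  for (i in seq_len(n)) {
    if (config$multi_exon) {
      n_ex <- sample(2:3, 1)
      cuts <- sort(sample.int(total[i] - 1L, n_ex - 1L))
      chunk <- diff(c(0L, cuts, total[i]))
      introns <- sample(200:1000, n_ex - 1, replace = TRUE)
      ex_start <- pos + c(0L, cumsum(chunk[-n_ex] + introns))
      exons <- cbind(ex_start, ex_start + chunk)
    } else {
      exons <- cbind(pos, pos + total[i])
    }
    skeleton <- transcript_model(genes[i], paste0(genes[i], ".T1"), "chr1",
                                 strand[i], exons)
    cds_g <- spliced_interval_to_genomic(skeleton, len5[i], len5[i] + lencds[i])
    models[[i]] <- transcript_model(genes[i], paste0(genes[i], ".T1"), "chr1",
                                    strand[i], exons, cds_g)
    gspan <- range(exons)
    gtf <- c(gtf,
             gtf_line("chr1", "gene", gspan[1], gspan[2], strand[i], genes[i]),
             gtf_line("chr1", "transcript", gspan[1], gspan[2], strand[i],
                      genes[i], paste0(genes[i], ".T1")),
             vapply(seq_len(nrow(exons)), function(j) {
               gtf_line("chr1", "exon", exons[j, 1], exons[j, 2], strand[i],
                        genes[i], paste0(genes[i], ".T1"))
             }, ""),
             vapply(seq_len(nrow(cds_g)), function(j) {
               gtf_line("chr1", "CDS", cds_g[j, 1], cds_g[j, 2], strand[i],
                        genes[i], paste0(genes[i], ".T1"))
             }, ""))
    pos <- gspan[2] + 10000L
  }
  gtf_path <- file.path(out_dir, "annotation.gtf")
  writeLines(gtf, gtf_path)

  # peaks: one planted peak per methylated, filter-passing gene per stage,
  # jittered per replicate; optional sub-threshold decoys
  classes <- list(fetal = class1, adult = class2)
  peak_paths <- list()
  for (st in stages) {
    # preallocated accumulators, one slot per (peak, replicate, exon-piece)
    cap <- max(64L, n * 32L * config$n_replicates)
    a_start <- integer(cap); a_end <- integer(cap); a_name <- character(cap)
    a_sigv <- numeric(cap); a_qv <- numeric(cap); a_rep <- integer(cap)
    k <- 0L
    push <- function(gmat, name, sigv, qv, r) {
      for (j in seq_len(nrow(gmat))) {
        k <<- k + 1L
        a_start[k] <<- gmat[j, 1]; a_end[k] <<- gmat[j, 2]
        a_name[k] <<- name; a_sigv[k] <<- sigv
        a_qv[k] <<- qv; a_rep[k] <<- r
      }
    }
    for (i in seq_len(n)) {
      cls <- classes[[st]][i]
      if (cls == "NMG" || fail5[i]) next
      sp <- place_peaks(cls, len5[i], lencds[i], len3[i],
                        config$peak_len_range, config$coverage_target)
      for (p in seq_len(nrow(sp))) {
        pl <- sp[p, 2] - sp[p, 1]
        jmax <- config$jitter_frac / 2 * pl
        for (r in seq_len(config$n_replicates)) {
          shift <- if (jmax > 0) as.integer(round(stats::runif(1, -jmax, jmax))) else 0L
          s <- max(0L, min(sp[p, 1] + shift, total[i] - pl))
          gmat <- spliced_interval_to_genomic(models[[i]], s, s + pl)
          push(gmat, sprintf("%s_%s_pk%d_rep%d", genes[i], st, p, r),
               stats::runif(1, 3, 8), stats::runif(1, 2, 6), r)
        }
      }
      if (config$decoy_rate > 0 && stats::runif(1) < config$decoy_rate) {
        pl <- config$peak_len_range[1]
        ds <- sample.int(total[i] - pl + 1L, 1L) - 1L
        gmat <- spliced_interval_to_genomic(models[[i]], ds, ds + pl)
        sigv <- stats::runif(1, 1, 1.9)
        qv <- stats::runif(1, 0.2, 1.0)
        for (r in seq_len(config$n_replicates)) {
          push(gmat, sprintf("%s_%s_decoy", genes[i], st), sigv, qv, r)
        }
      }
    }
    peak_paths[[st]] <- vapply(seq_len(config$n_replicates), function(r) {
      p <- file.path(out_dir, sprintf("peaks_%s_rep%d.narrowPeak", st, r))
      sel <- which(a_rep[seq_len(k)] == r)
      sel <- sel[order(a_start[sel])]
      df <- data.frame(chrom = rep("chr1", length(sel)),
                       start = a_start[sel], end = a_end[sel],
                       name = a_name[sel],
                       score = as.integer(round(a_sigv[sel] * 100)),
                       strand = rep(".", length(sel)),
                       signalValue = round(a_sigv[sel], 4),
                       pValue = round(a_qv[sel] + 0.5, 4),
                       qValue = round(a_qv[sel], 4),
                       peak = rep(-1L, length(sel)),
                       stringsAsFactors = FALSE)
      utils::write.table(df, p, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
      p
    }, "")
  }

  # expression and counts with planted m6A-level/expression coupling
  expr <- list()
  expr$fetal <- stats::rlnorm(n, config$expr_meanlog, config$expr_sdlog)
  de <- stats::runif(n) < config$de_frac
  de_sign <- sample(c(-1, 1), n, replace = TRUE)
  de_lfc <- ifelse(de, de_sign * config$de_lfc, stats::rnorm(n, 0, 0.05))
  expr$adult <- expr$fetal * 2^de_lfc

  level <- list()
  for (st in stages) {
    meth <- classes[[st]] != "NMG"
    lv <- rep(1, n)
    if (any(meth)) {
      z <- as.numeric(scale(log(expr[[st]][meth])))
      eps <- stats::rnorm(sum(meth))
      log2lv <- log2(config$m6a_effect) + config$m6a_level_sdlog2 *
        (config$m6a_expr_rho * z + sqrt(1 - config$m6a_expr_rho^2) * eps)
      lv[meth] <- 2^log2lv
    }
    level[[st]] <- lv
  }

  size <- 1 / config$nb_dispersion
  count_paths <- character(0)
  sample_sheet <- list()
  for (st in stages) {
    cols <- list(gene_id = genes, length = total)
    for (r in seq_len(config$n_replicates)) {
      depth <- stats::runif(1, 0.8, 1.2)
      mu <- expr[[st]] * (total / 1000) * depth
      nm <- sprintf("%s_input_%d", st, r)
      cols[[nm]] <- stats::rnbinom(n, mu = mu, size = size)
      sample_sheet[[nm]] <- data.frame(sample = nm, role = "input",
                                       stage = st, replicate = r)
    }
    for (r in seq_len(config$n_replicates)) {
      depth <- stats::runif(1, 0.8, 1.2)
      mu <- expr[[st]] * level[[st]] * (total / 1000) * depth
      nm <- sprintf("%s_IP_%d", st, r)
      cols[[nm]] <- stats::rnbinom(n, mu = mu, size = size)
      sample_sheet[[nm]] <- data.frame(sample = nm, role = "IP",
                                       stage = st, replicate = r)
    }
    p <- file.path(out_dir, sprintf("counts_%s.tsv", st))
    utils::write.table(as.data.frame(cols, check.names = FALSE), p,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    count_paths[st] <- p
  }
  samples_path <- file.path(out_dir, "samples.tsv")
  utils::write.table(do.call(rbind, sample_sheet), samples_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # tissue panel with known specificity
  specific <- stats::runif(n) < config$spec_frac
  spec_tissue <- sample.int(max(config$n_tissues, 1), n, replace = TRUE)
  panel <- matrix(0, nrow = n, ncol = config$n_tissues,
                  dimnames = list(genes,
                                  sprintf("tissue%02d", seq_len(config$n_tissues))))
  for (i in seq_len(n)) {
    if (specific[i]) {
      panel[i, ] <- expr$fetal[i] * 0.02
      panel[i, spec_tissue[i]] <- expr$fetal[i] * 5
    } else {
      panel[i, ] <- expr$fetal[i] * stats::rlnorm(config$n_tissues, 0, 0.1)
    }
  }
  panel_path <- file.path(out_dir, "tissue_panel.tsv")
  utils::write.table(data.frame(gene_id = genes, panel, check.names = FALSE),
                     panel_path, sep = "\t", quote = FALSE, row.names = FALSE)

  truth <- data.frame(
    gene_id = genes, fetal_class = class1, adult_class = class2,
    passes_filter = !fail5, len5utr = len5, lencds = lencds, len3utr = len3,
    strand = strand,
    expr_fetal = expr$fetal, expr_adult = expr$adult,
    m6a_level_fetal = level$fetal, m6a_level_adult = level$adult,
    de_planted = de, de_log2fc = de_lfc,
    tissue_specific = specific, stringsAsFactors = FALSE
  )
  truth_path <- file.path(out_dir, "truth.tsv")
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  structure(list(gtf = gtf_path, peaks = peak_paths, counts = count_paths,
                 samples = samples_path, tissue_panel = panel_path,
                 truth_path = truth_path, truth = truth, config = config,
                 out_dir = out_dir),
            class = "SyntheticDataset")
}

#' Truth report with realized parameters
#'
#' Returns the planted per-gene truth table and, alongside the target
#' correlation, the correlation actually realized in the emitted count
#' tables: Pearson r between log2 m6A level (mean IP TPM over mean input
#' TPM) and log2 expression (mean input TPM) over methylated,
#' filter-passing genes, per stage.
#'
#' @param ds a `SyntheticDataset`.
#' @param path optional TSV path to (re)write the truth table to.
#' @return list with `truth` (data.frame), `target_rho`, and
#'   `realized_rho` (named by stage).
#' @export
truth_report <- function(ds, path = NULL) {
  stopifnot(inherits(ds, "SyntheticDataset"))
  realized <- vapply(names(ds$counts), function(st) {
    ct <- read_count_table(ds$counts[[st]], ds$samples)
    roles <- ct$samples$role[match(colnames(ct$counts), ct$samples$sample)]
    tp <- tpm(ct$counts, ct$lengths)
    ip <- rowMeans(tp[, roles == "IP", drop = FALSE])
    inp <- rowMeans(tp[, roles == "input", drop = FALSE])
    lvl <- m6a_level(ip, inp)
    meth <- ds$truth[[paste0(st, "_class")]] != "NMG" & ds$truth$passes_filter
    ok <- meth & lvl$flag == "ok" & lvl$level > 0
    pearson_correlation(log2(lvl$level[ok]), log2(inp[ok]))$statistic
  }, 0)
  if (!is.null(path)) {
    utils::write.table(ds$truth, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  list(truth = ds$truth, target_rho = ds$config$m6a_expr_rho,
       realized_rho = realized)
}
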