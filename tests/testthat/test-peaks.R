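# Peak I/O, filtering, reproducibility, merging, annotation and signal
# averaging, checked against per-base brute-force oracles.

write_narrowpeak <- function(df, path = tempfile(fileext = ".narrowPeak")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  path
}

test_that("narrowPeak reader decodes signalValue and qValue columns", {
  p <- write_narrowpeak(data.frame(
    "chr1", c(100L, 500L), c(200L, 700L), c("p1", "p2"), 0L, ".",
    c(3.5, 6.1), c(2.5, 4.5), c(2.0, 4.0), -1L))
  ps <- read_peaks(p, sample_id = "s1")
  expect_equal(nrow(ps), 2)
  expect_equal(ps$fold_enrichment, c(3.5, 6.1))
  expect_equal(ps$fdr, c(1e-2, 1e-4))
  expect_equal(attr(ps, "provenance"), "s1")
})

test_that("empty and BED6 inputs are handled; bad records rejected", {
  empty <- tempfile(); file.create(empty)
  expect_equal(nrow(read_peaks(empty)), 0)

  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t60\ta\t0\t.", "chr1\t100\t160\tb\t0\t.",
               "chr2\t5\t25\tc\t0\t."), bed)
  ps <- read_peaks(bed, "s2")
  expect_equal(nrow(ps), 3)
  expect_true(all(is.infinite(ps$fold_enrichment)))
  expect_true(all(ps$fdr == 0))

  bad <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t60\ta\t0\t.", "chr1\t80\t70\tb\t0\t."), bad)
  expect_warning(ps2 <- read_peaks(bad), "start >= end")
  expect_equal(nrow(ps2), 1)

  nonnum <- tempfile(fileext = ".bed")
  writeLines("chr1\t10\t60\ta\txx\t.", nonnum)
  expect_error(read_peaks(nonnum), "non-numeric")
})

test_that("enrichment/FDR filter is strict on both boundaries", {
  ps <- peakset_from_mat(rbind(c(0, 10), c(20, 30), c(40, 50)))
  ps$fold_enrichment <- c(2.5, 1.9, 3.0)
  ps$fdr <- c(0.01, 0.001, 0.2)
  kept <- filter_peaks(ps)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$start, 0)

  boundary <- peakset_from_mat(rbind(c(0, 10), c(20, 30)))
  boundary$fold_enrichment <- c(2.0, 2.1)
  boundary$fdr <- c(0.01, 0.05)
  expect_equal(nrow(filter_peaks(boundary)), 0)
})

test_that("filtering is monotone in its thresholds", {
  set.seed(5)
  ps <- peakset_from_mat(random_intervals(200, 10000))
  ps$fold_enrichment <- runif(200, 0, 6)
  ps$fdr <- runif(200, 0, 0.2)
  base_ids <- paste(filter_peaks(ps)$start, filter_peaks(ps)$end)
  for (mf in c(2.5, 3, 4)) {
    expect_true(all(paste(filter_peaks(ps, min_fold = mf)$start,
                          filter_peaks(ps, min_fold = mf)$end) %in% base_ids))
  }
  for (mq in c(0.03, 0.01)) {
    expect_true(all(paste(filter_peaks(ps, max_fdr = mq)$start,
                          filter_peaks(ps, max_fdr = mq)$end) %in% base_ids))
  }
})

test_that("replicate reproducibility uses query-fraction overlap", {
  a <- peakset_from_mat(rbind(c(100, 200)))
  b <- peakset_from_mat(rbind(c(150, 300)))
  # overlap 50/100 = 0.5 >= 0.5: a retained; b (150/150 vs a? 50/150 < 0.5)
  out <- reproducible_peaks(a, b)
  expect_equal(unname(cbind(out$start, out$end)), rbind(c(100L, 200L)))

  b2 <- peakset_from_mat(rbind(c(160, 300)))
  out2 <- reproducible_peaks(a, b2)
  expect_equal(nrow(out2), 0)

  ident <- peakset_from_mat(rbind(c(0, 50), c(40, 90), c(200, 250)))
  out3 <- reproducible_peaks(ident, ident)
  merged <- merge_peaks(ident)
  expect_equal(cbind(out3$start, out3$end), cbind(merged$start, merged$end))
})

test_that("merge coalesces overlapping and book-ended intervals", {
  ps <- peakset_from_mat(rbind(c(0, 10), c(5, 20)))
  m <- merge_peaks(ps)
  expect_equal(cbind(m$start, m$end), cbind(0L, 20L))

  booked <- peakset_from_mat(rbind(c(0, 10), c(10, 20)))
  m2 <- merge_peaks(booked)
  expect_equal(cbind(m2$start, m2$end), cbind(0L, 20L))

  # idempotence
  expect_equal(as.data.frame(merge_peaks(m2)), as.data.frame(m2))
})

test_that("interval operations agree with the per-base oracle on random genomes", {
  set.seed(77)
  for (i in 1:60) {
    G <- sample(500:10000, 1)
    a <- random_intervals(sample(1:20, 1), G, max_len = min(500, G - 1))
    b <- random_intervals(sample(1:20, 1), G, max_len = min(500, G - 1))

    m <- merge_peaks(peakset_from_mat(a))
    expect_equal(unname(cbind(m$start, m$end)), unname(oracle_merge(a, G)))

    frac <- sample(c(0, 0.25, 0.5, 0.9), 1)
    r <- reproducible_peaks(peakset_from_mat(a), peakset_from_mat(b),
                            min_frac = frac)
    expect_equal(unname(cbind(r$start, r$end)),
                 unname(oracle_reproducible(a, b, frac, G)))
  }
})

test_that("reproducible_peaks with zero threshold reduces to a merge", {
  set.seed(9)
  a <- peakset_from_mat(random_intervals(15, 5000))
  out <- reproducible_peaks(a, a, min_frac = 0)
  m <- merge_peaks(a)
  expect_equal(cbind(out$start, out$end), cbind(m$start, m$end))
})

test_that("peak annotation follows the stated priority order", {
  # long gene: 5'UTR [5000,6000), CDS [6000,10500), 3'UTR [10500,12000);
  # promoter [2000,8000) overlaps the 5'UTR and the early CDS
  t <- transcript_model("gA", "gA.T1", "chr1", "+",
                        exons = rbind(c(5000, 12000)),
                        cds = rbind(c(6000, 10500)))
  t2 <- transcript_model("gB", "gB.T1", "chr1", "+",
                         exons = rbind(c(20000, 20600), c(24000, 25000)),
                         cds = rbind(c(20100, 20600), c(24000, 24900)))
  regions <- list(gene_regions(t), gene_regions(t2))
  ps <- peakset_from_mat(rbind(
    c(5050, 5150),     # 5'UTR and promoter: fiveUTRs wins the priority
    c(3000, 3100),     # upstream of TSS: Promoters
    c(6500, 6600),     # CDS inside the promoter window: Promoters wins
    c(10800, 10900),   # threeUTRs
    c(9000, 9100),     # CDS beyond the promoter -> Exons
    c(23200, 23400),   # intron of gB (past its promoter window)
    c(500, 600)        # nothing
  ))
  ann <- annotate_peaks(ps, regions)
  expect_equal(ann$region,
               c("fiveUTRs", "Promoters", "Promoters", "threeUTRs", "Exons",
                 "Introns", "Intergenic"))
  expect_equal(ann$gene_id[1], "gA")
  expect_true(is.na(ann$gene_id[7]))

  # with the promoter category disabled (transcript-region annotation),
  # the early-CDS peak falls through to Exons
  regions0 <- list(gene_regions(t, promoter_width = 0),
                   gene_regions(t2, promoter_width = 0))
  ann0 <- annotate_peaks(ps, regions0)
  expect_equal(ann0$region[3], "Exons")
  expect_equal(ann0$region[2], "Intergenic")
})

test_that("regional frequencies normalise over 5'UTR/CDS/3'UTR", {
  ann <- data.frame(chrom = "chr1", start = 0, end = 1,
                    region = rep("fiveUTRs", 10), gene_id = "g")
  f <- region_frequency(ann)
  expect_equal(unname(f$proportions["fiveUTRs"]), 1)

  ann2 <- data.frame(chrom = "chr1", start = 0, end = 1,
                     region = c(rep("fiveUTRs", 2), rep("Exons", 5),
                                rep("threeUTRs", 3), "Introns", "Intergenic"),
                     gene_id = "g")
  f2 <- region_frequency(ann2)
  expect_equal(unname(f2$proportions), c(0.2, 0.5, 0.3))
  expect_error(region_frequency(ann2[0, ]), "no annotated")

  # two stages compared by the two-proportion z-test on 5'UTR frequency
  z <- two_proportion_ztest(20, 100, 10, 100)
  expect_gt(z$statistic, 0)
  expect_lt(z$pvalue, 0.1)
})

test_that("region mean signal equals the per-base average", {
  sig <- data.frame(chrom = "chr1", start = c(0, 50), end = c(50, 100),
                    value = c(1, 1))
  iv <- data.frame(chrom = "chr1", start = 10, end = 90)
  expect_equal(region_mean_signal(iv, sig), 1)

  half <- data.frame(chrom = "chr1", start = c(0, 50), end = c(50, 100),
                     value = c(0, 1))
  expect_equal(region_mean_signal(data.frame(chrom = "chr1", start = 0,
                                             end = 100), half), 0.5)

  # undefined when no base is covered
  expect_true(is.na(region_mean_signal(
    data.frame(chrom = "chr1", start = 500, end = 600), sig)))

  set.seed(31)
  for (i in 1:40) {
    G <- sample(200:2000, 1)
    n_seg <- sample(3:10, 1)
    brk <- sort(sample(seq(0, G, by = 10), n_seg + 1))
    brk <- unique(brk)
    if (length(brk) < 3) next
    sig <- data.frame(chrom = "chr1", start = brk[-length(brk)],
                      end = brk[-1], value = round(rnorm(length(brk) - 1), 3))
    iv <- as.data.frame(random_intervals(sample(1:5, 1), G, max_len = 150))
    names(iv) <- c("start", "end")
    iv$chrom <- "chr1"
    expect_equal(region_mean_signal(iv, sig),
                 oracle_region_mean(iv, sig, G))
  }
})
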