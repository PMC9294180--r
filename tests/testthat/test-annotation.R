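# Gene-model parsing, transcript selection/filtering, and metatranscript
# coordinate mapping.

test_that("GTF parsing derives UTR lengths from exon/CDS structure", {
  p <- write_toy_gtf(list(
    list(gene = "A", tx = "A.T1", strand = "+",
         exons = rbind(c(0, 300)), cds = rbind(c(100, 250)))
  ))
  m <- read_gtf(p)[["A.T1"]]
  expect_equal(m$len5utr, 100)
  expect_equal(m$lencds, 150)
  expect_equal(m$len3utr, 50)
  expect_true(m$cds_complete)

  # identical structure on the minus strand mirrors the UTRs
  p2 <- write_toy_gtf(list(
    list(gene = "A", tx = "A.T1", strand = "-",
         exons = rbind(c(0, 300)), cds = rbind(c(100, 250)))
  ))
  m2 <- read_gtf(p2)[["A.T1"]]
  expect_equal(m2$len5utr, 50)
  expect_equal(m2$lencds, 150)
  expect_equal(m2$len3utr, 100)
})

test_that("spliced CDS length sums across exons (enumeration check)", {
  m <- transcript_model("A", "T1", "chr1", "+",
                        exons = rbind(c(0, 100), c(200, 300)),
                        cds = rbind(c(50, 100), c(200, 260)))
  expect_equal(m$spliced_length, 200)
  expect_equal(m$lencds, 110)
  expect_equal(m$len5utr, 50)
  expect_equal(m$len3utr, 40)
  # enumeration: count exonic bases inside CDS one by one
  bases <- c(0:99, 200:299)
  in_cds <- (bases >= 50 & bases < 100) | (bases >= 200 & bases < 260)
  expect_equal(sum(in_cds), m$lencds)
  expect_false(m$cds_complete)  # 110 is not a multiple of 3
})

test_that("longest-transcript selection maximises spliced length with id tie-break", {
  mk <- function(g, tx, len) {
    transcript_model(g, tx, "chr1", "+", exons = rbind(c(0, len)))
  }
  models <- list(mk("A", "A.T1", 1000), mk("A", "A.T2", 1500),
                 mk("B", "B.T1", 700),
                 mk("C", "T2", 1200), mk("C", "T1", 1200))
  chosen <- select_longest_transcript(models)
  expect_equal(chosen[["A"]]$transcript_id, "A.T2")
  expect_equal(chosen[["B"]]$transcript_id, "B.T1")
  expect_equal(chosen[["C"]]$transcript_id, "T1")
})

test_that("length filters are strict, so boundary transcripts survive", {
  mk <- function(g, l5, lc, l3) {
    total <- l5 + lc + l3
    transcript_model(g, paste0(g, ".T1"), "chr1", "+",
                     exons = rbind(c(0, total)),
                     cds = rbind(c(l5, l5 + lc)))
  }
  chosen <- list(A = mk("A", 49, 300, 200),    # 5'UTR one short
                 B = mk("B", 50, 100, 100),    # exactly at all bounds
                 C = mk("C", 100, 99, 300),    # CDS short
                 D = mk("D", 100, 300, 99),    # 3'UTR short
                 E = mk("E", 200, 600, 400))
  kept <- filter_transcripts(chosen)
  expect_setequal(names(kept), c("B", "E"))

  # rule applied gene by gene: 10 genes, 3 violating one bound each
  ten <- c(lapply(1:7, function(i) mk(paste0("K", i), 60, 300, 150)),
           list(mk("V1", 10, 300, 150), mk("V2", 60, 60, 150),
                mk("V3", 60, 300, 50)))
  names(ten) <- vapply(ten, `[[`, "", "gene_id")
  expect_length(filter_transcripts(ten), 7)
})

test_that("genomic positions map to metatranscript windows", {
  t_plus <- transcript_model("A", "T1", "chr1", "+",
                             exons = rbind(c(1000, 1500)),
                             cds = rbind(c(1100, 1400)))
  first <- genomic_to_meta(t_plus, 1000)
  expect_equal(first$region, "fiveUTR")
  expect_equal(first$fraction, 0)
  expect_equal(first$window_index, 1)

  t_intron <- transcript_model("A", "T1", "chr1", "+",
                               exons = rbind(c(0, 100), c(200, 500)),
                               cds = rbind(c(50, 100), c(200, 350)))
  expect_null(genomic_to_meta(t_intron, 150))

  # minus strand: the genomically smallest exonic base is the transcript's
  # 3' extremity -> last window
  t_minus <- transcript_model("A", "T1", "chr1", "-",
                              exons = rbind(c(1000, 1500)),
                              cds = rbind(c(1100, 1400)))
  last <- genomic_to_meta(t_minus, 1000)
  expect_equal(last$region, "threeUTR")
  expect_equal(last$window_index, 50)
  # enumeration: base 1000 is spliced position 499 of 500, i.e. the last
  # base of the 100-nt 3'UTR
  expect_equal(last$fraction, 99 / 100)
})

test_that("window boundaries partition each region's spliced bases", {
  set.seed(101)
  for (i in 1:25) {
    t <- random_toy_transcript()
    counts <- integer(50)
    for (sp in seq_len(t$spliced_length) - 1L) {
      g <- meta_to_genomic(t, sp)
      mc <- genomic_to_meta(t, g)
      counts[mc$window_index] <- counts[mc$window_index] + 1L
    }
    expect_equal(sum(counts[1:10]), t$len5utr)
    expect_equal(sum(counts[11:30]), t$lencds)
    expect_equal(sum(counts[31:50]), t$len3utr)
    # near-equal windows: sizes differ by at most 1 within a region
    for (block in list(1:10, 11:30, 31:50)) {
      expect_lte(diff(range(counts[block])), 1)
    }
  }
})

test_that("spliced/genomic mapping round-trips on random transcripts", {
  set.seed(202)
  for (i in 1:20) {
    t <- if (i %% 2 == 0) random_toy_transcript() else
      transcript_model("G", "G.T1", "chr1", sample(c("+", "-"), 1),
                       exons = rbind(c(100, 400), c(600, 900), c(1200, 1500)),
                       cds = rbind(c(200, 400), c(600, 800)))
    sps <- sample.int(t$spliced_length, 50) - 1L
    for (sp in sps) {
      g <- meta_to_genomic(t, sp)
      # inverse direction: genomic base maps back to the same spliced pos
      back <- m6Atopo:::genomic_intervals_to_spliced(t, cbind(g, g + 1L))
      expect_equal(unname(back[1, 1]), sp)
    }
  }
})

test_that("mirrored locus on the opposite strand yields identical meta coordinates", {
  L <- 2000L
  exons <- rbind(c(100, 400), c(700, 1100))
  cds <- rbind(c(200, 400), c(700, 950))
  fwd <- transcript_model("G", "T1", "chr1", "+", exons, cds)
  mirror <- function(m) cbind(L - m[, 2], L - m[, 1])
  rev <- transcript_model("G", "T1", "chr1", "-", mirror(exons), mirror(cds))
  expect_equal(rev$len5utr, fwd$len5utr)
  expect_equal(rev$len3utr, fwd$len3utr)
  for (sp in c(0L, 57L, 300L, fwd$spliced_length - 1L)) {
    g <- meta_to_genomic(fwd, sp)
    expect_equal(genomic_to_meta(rev, L - 1L - g),
                 genomic_to_meta(fwd, g))
  }
})

test_that("transcript isoforms are tallied per gene before selection", {
  mk <- function(g, tx) transcript_model(g, tx, "chr1", "+",
                                         exons = rbind(c(0, 100)))
  models <- list(mk("A", "A.T1"), mk("A", "A.T2"), mk("B", "B.T1"))
  expect_equal(transcript_counts(models), c(A = 2L, B = 1L))
  expect_false("C" %in% names(transcript_counts(models)))
})

test_that("gene_regions derives promoter, introns and stop flank", {
  t <- transcript_model("A", "T1", "chr1", "+",
                        exons = rbind(c(5000, 5400), c(5800, 6600)),
                        cds = rbind(c(5100, 5400), c(5800, 6100)))
  r <- gene_regions(t)
  expect_equal(r$promoter, cbind(2000L, 8000L), ignore_attr = TRUE)
  expect_equal(r$introns, cbind(5400L, 5800L), ignore_attr = TRUE)
  # stop codon at spliced position len5 + lencds; flank spans 100 nt each
  # side across the CDS/3'UTR junction
  flank_len <- sum(r$stop_flank[, 2] - r$stop_flank[, 1])
  expect_equal(flank_len, 200)
  # short 3'UTR truncates the downstream side only
  t2 <- transcript_model("B", "T1", "chr1", "+",
                         exons = rbind(c(0, 1000)),
                         cds = rbind(c(100, 960)))
  r2 <- gene_regions(t2)
  expect_equal(sum(r2$stop_flank[, 2] - r2$stop_flank[, 1]), 140)
})
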