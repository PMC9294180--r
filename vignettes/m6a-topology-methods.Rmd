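---
title: "Classifying m6A topology and measuring its developmental transitions"
author: "m6Atopo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying m6A topology and measuring its developmental transitions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m6Atopo)
```

## The problem

N6-methyladenosine (m6A) is the most common internal mRNA modification.
MeRIP-seq detects it as enriched intervals (peaks) in an
immunoprecipitated (IP) library relative to an input library.  Where m6A
sits along a transcript matters: 5'UTR m6A influences cap-independent
translation, stop-codon-proximal m6A is the classical metagene signal,
and 3'UTR m6A interacts with polyadenylation and stability.  `m6Atopo`
classifies protein-coding genes by their m6A *topology* — the
distribution of peak density along a normalised transcript model — into
five groups:

* **NMG** — no or little m6A;
* **5'MG** — m6A concentrated in the 5'UTR;
* **CMG** — m6A concentrated in the CDS body;
* **SMG** — m6A concentrated around the stop codon;
* **3'MG** — m6A concentrated in the 3'UTR.

Comparing assignments between two biological stages (e.g. fetal vs adult
tissue) then quantifies *topological transitions*: which genes lose
5'UTR methylation, which gain stop-codon methylation, and how stable
each group is.

## The metatranscript model

One representative transcript is chosen per gene: the transcript with
the greatest spliced length, ties broken by lexicographically smallest
transcript id.  Genes whose representative transcript has a 5'UTR
shorter than 50 nt, a CDS shorter than 100 nt, or a 3'UTR shorter than
100 nt are removed (strict `<`, so boundary lengths survive); windows
over very short regions would be sub-nucleotide.

The spliced 5'UTR, CDS and 3'UTR are divided into 10, 20 and 20 windows.
Windows within a region differ in size by at most one nucleotide; the
remainder bases are assigned one per window starting from the 5' end, so
windowing is deterministic.  All lengths are spliced (intron-free)
nucleotides: filters and windows describe the mRNA, not the locus.
Internally every genomic interval is 0-based half-open (BED convention);
GTF records are converted on read.

Each cell of the resulting genes-by-50 matrix holds the fraction of the
window's spliced bases covered by at least one merged peak — a per-base
density in [0, 1], not a binary overlap flag.  A gene without peaks has
an all-zero row.

## Peak handling

`read_peaks()` accepts ENCODE narrowPeak (signalValue as fold
enrichment; qValue interpreted as -log10 FDR per the ENCODE convention)
or BED6, which is treated as pre-filtered (peak calling itself is out of
scope; the package consumes peak files).  Confidence filtering keeps
peaks with fold enrichment strictly greater than 2 and FDR strictly
below 0.05.  Replicate reproducibility follows `bedtools intersect -f
0.5` semantics: a peak survives when at least half of *its own* length
is covered by the other replicate's peaks, applied symmetrically, after
which survivors are merged (book-ended intervals coalesce, matching
`bedtools merge`).  More than two replicates are reduced by sequential
pairwise intersection, with a warning, since the design assumes
replicate pairs.

Peak-to-gene annotation uses the fixed priority fiveUTRs > Promoters >
threeUTRs > Exons > Introns (any overlap of at least 1 bp; ties across
genes go to the smallest gene id; no hit means Intergenic).  The
promoter is TSS ± 3000 bp, a conventional default.  One consequence
worth knowing: for genes whose genomic span is shorter than 3 kb the
promoter window covers the whole gene body and, by priority, absorbs
CDS/3'UTR peaks.  `run_all()` therefore computes the mRNA
region-frequency table (the share of peaks in 5'UTR/CDS/3'UTR) from a
promoter-free annotation (`gene_regions(..., promoter_width = 0)`);
the full priority remains the default for genomic annotation.

## Quantification

TPM is computed exactly as counts x 10^6 / (length x sum(counts /
length)), so every column sums to one million.  The m6A level of a gene
is IP TPM divided by input TPM; genes with zero input are flagged
`input_too_low` and excluded from correlation analyses rather than given
a pseudocounted ratio, keeping the level scale interpretable.

`tmm_factors()` implements trimmed-mean-of-M-values scaling with the
published default trims (30% of M-values and 5% of A-values per tail)
and the upper-quartile rule for automatic reference choice.  Two
deliberate details differ from the common implementation.  First, the
factor is a multiplier on counts that absorbs library size: a sample
sequenced twice as deeply gets a factor half as large (two identical
libraries where one is doubled yield factors (sqrt(2), 1/sqrt(2)) after
geometric-mean rescaling).  Second, M, A and the inverse-variance
binomial weights are computed on relative abundances, which are
invariant under library scaling; the library-size log-ratio is added
back analytically.  This makes depth absorption *exact*, untouched by
floating-point tie-breaking in the rank trims.

Differential expression and differential methylation use the same rule:
significant iff p < 0.05 and |log2FC| > 1, both strict.  P-values come
from `rate_ratio_test()`, an exact conditional binomial test: given
countsA + countsB events, countsA is Binomial with success probability
scaleA/(scaleA + scaleB) under equal rates; the two-sided p doubles the
smaller tail, capped at 1, and the fold change uses a 0.5 pseudocount.
A negative-binomial exact test with dispersion estimation would need
replicate structure the two-stage design does not guarantee; the
conditional binomial test is exact, assumption-light, and the
thresholded gene sets — not the test internals — are the scientific
object here.

## Clustering and labelling

Genes are clustered with Euclidean k-means, k = 5.  Initialisation
matters more than iteration here: window profiles have substantial
within-group spread, so purely random starts frequently seed two centres
in one diffuse group and none in a small tight one.  `kmeans_cluster()`
therefore evaluates one deterministic start at the five canonical
topology archetypes (all-zero, 5'UTR block, CDS block, stop-flank block,
3'UTR block, scaled to the data's mean positive cell) plus `n_init = 10`
kmeans++ seedings, and keeps the solution with the smallest
within-cluster sum of squares.  Rows are canonicalised into
lexicographic order before any RNG use, so results are deterministic
given a seed and invariant to gene order.  Each gene's final assignment
is its nearest centroid, ties resolved towards the smallest cluster id.

Centroids are labelled by a fixed rule: the centroid with the smallest
overall mean is NMG and must be below half of the runner-up (otherwise
no cluster is clearly unmethylated and an error suggests a different
seed or the `kmeans_diagnostic()` scan over k).  The remaining four take
the label of their maximal meta-region mean: windows 1-10 (5'UTR), 11-27
(CDS body), 28-32 (stop flank, approximately +/-100 nt around the stop
codon in window space), 33-50 (3'UTR body).  The labelling must be
bijective.  If more than 99% of genes have all-zero profiles, k-means
would be degenerate and every gene is reported as NMG directly.
Classification always uses k = 5; `kmeans_diagnostic()` reports
within-cluster variance for k = 2..8 as a sanity check only.

## Transitions

Transitions are measured on the intersection of the two stages' filtered
gene universes.  The *overlap ratio* of a group is the diagonal count
over the group's marginal in a chosen reference stage; the *transition
ratio* matrix is the row-normalised 5x5 cross-tabulation with stage 1
(fetal) as reference.  Four derived sets capture the dominant
developmental changes: adult-loss 5'MGs (fetal 5'MG to adult NMG),
adult-retained 5'MGs, adult-gain SMGs (adult SMG, fetal not SMG) and
adult-retained SMGs.  Three-stage chains are handled by composing
pairwise tables.

## Statistics

* `tau()`: tissue-specificity index, sum(1 - x/max(x))/(n-1); 0 means
  broadly expressed, 1 means single-tissue.  Computed on linear TPM by
  default (a log2(x+1) option exists but is off), undefined for
  all-zero genes.
* `two_proportion_ztest()`: pooled-proportion z; on a 2x2 table z
  squared equals the Pearson chi-square statistic without continuity
  correction, which is why the pooled (not unpooled) variant was chosen.
* `chi2_test()`: Pearson chi-square on 2xk tables, no continuity
  correction, error on zero marginals.
* `fisher_exact()`: two-sided exact p as the sum of hypergeometric
  probabilities no larger than the observed table's (relative tie
  tolerance 1 + 1e-7, the standard convention).
* `odds_ratio()`: cross-product ratio; the Haldane-Anscombe +0.5
  correction is applied only when an off-diagonal cell is zero, and
  flagged.
* `geneset_enrichment()`: per-set 2x2 Fisher tests with BH adjustment
  across the sets of one query; significance at adjusted p < 0.05.  The
  recommended universe is the filtered gene set — the same universe the
  clustering sees — not the whole annotation.

## The synthetic-data generator

`generate_dataset()` emulates the inputs of a two-stage MeRIP-seq study
with known truth, so that every pipeline stage can be checked
end-to-end.  Defaults, chosen once as the study conditions:

* 2000 genes, equal class probabilities over the five groups;
* transition matrix with 0.6 on the diagonal, except the 5'MG row where
  half of the fetal 5'MGs become adult NMGs (0.5), the signature
  developmental transition;
* spliced region lengths: 5'UTR 150-300 nt, CDS 300-1500 nt (multiples
  of 3), 3'UTR 250-800 nt; 5% of genes violate the 5'UTR filter to
  exercise the filtering path (they receive no peaks);
* peaks 100-150 nt with per-replicate boundary jitter of up to 20% of
  peak length, which always preserves the 50% reciprocal-overlap
  criterion; signal values 3-8x and FDRs 1e-2 to 1e-6, so every planted
  peak passes the default filters (optional decoys are emitted
  sub-threshold);
* negative-binomial counts (dispersion 0.05) around log-normal
  expression (meanlog 5, sdlog 1 on the natural scale), two replicates
  per library, per-sample depth factors 0.8-1.2;
* a 4x IP enrichment for methylated genes, modulated so that log2 m6A
  level and log2 expression have a planted correlation of -0.5 among
  methylated genes (a latent bivariate-normal coupling; NB counting
  noise attenuates the realised value slightly, which `truth_report()`
  measures rather than assumes);
* a 12-tissue expression panel in which 20% of genes are tissue-specific.

Peak placement is class-driven: 5'MG inside the 5'UTR, CMG inside the
CDS excluding its last 100 nt, 3'MG inside the 3'UTR excluding its first
100 nt, SMG with peak centres within +/-100 nt of the stop codon, NMG
none.  Within the target region, peaks *tile* the region (strata of
about one peak length, one peak per stratum, covering ~70% of the region
in expectation) rather than landing at a single random position.  This
models what a topology group is — enrichment across a genic region, as
in per-group metagene profiles — and makes the planted classes coherent
in window space.  With isolated single peaks per gene, the within-class
positional variance would exceed the between-class separation and no
clustering method could (or should) recover the labels.

What the generator does **not** emulate: read-level noise and alignment
artifacts, sequence-motif placement (RRACH), isoform switching,
overlapping genes, chromosome structure (genes are laid head-to-tail
with 10 kb gaps, single-exon by default with a multi-exon mode for the
spliced-mapping logic), batch effects, and antibody-specific biases.
Passing the recovery tests therefore demonstrates that the pipeline's
logic is correct under its stated model, not that real tissues will
yield equally clean groups — on real data the groups are overlapping
clouds and recovery rates are not meaningful in the same way.

## Numerical choices and degenerate inputs

* Coordinates 0-based half-open everywhere internally; GTF (1-based
  closed) converted on read; BED written bit-exactly.
* Remainder bases in windowing go one per window from the 5' end.
* Tie-breaks: longest transcript by smallest transcript id; annotation
  gene ties by smallest gene id; nearest-centroid ties by smallest
  cluster id.
* k-means: seed 42 by default, 10 kmeans++ starts plus the archetype
  start, 300 iterations, handled through a canonical row order for
  order invariance.
* Degenerate inputs: all-zero count columns are an error naming the
  sample; zero marginals make chi-square an error and overlap ratios
  undefined (NA); zero covered bases make region means NA (distinct
  from 0); fewer than 10 genes surviving the TMM trims falls back to
  the untrimmed mean with a warning.

## Problem sizes

The shipped tests and the acceptance script run the classifier at 2000
genes, the transition analysis at 5000, the correlation recovery at
1000, and the interval-arithmetic oracles at 1000 random configurations
each — sizes at which every statistical recovery criterion is
well-powered while a complete run takes a few minutes on one core.

## Known limitations

* The per-gene window profile uses merged peak presence, not read-level
  coverage depth; two peaks of different strength contribute equally.
* The exact conditional binomial test ignores biological overdispersion;
  with replicated designs a dispersion-aware NB test is preferable.
* The centroid-labelling rule presumes the five-group structure; data
  without a clearly unmethylated cluster raise an error by design
  rather than silently mislabelling.
* Transition analysis treats stages as matched gene universes; genes
  filtered in only one stage are excluded, and reported separately by
  `cross_tab()`.
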