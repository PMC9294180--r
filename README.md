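# m6Atopo

Where N6-methyladenosine (m6A) sits along an mRNA — 5'UTR, CDS, around
the stop codon, 3'UTR — carries biological meaning, and that *topology*
changes during tissue development.  `m6Atopo` is an R package for
epitranscriptomics analysts working with MeRIP-seq peak data: it
classifies protein-coding genes into five m6A topology groups and
quantifies how genes move between groups across two biological stages
(e.g. fetal vs adult tissue), together with the expression and m6A-level
quantification and the statistics such analyses need.

## Method

For each gene the longest spliced transcript is selected, and genes with
a 5'UTR < 50 nt, CDS < 100 nt or 3'UTR < 100 nt are removed.  The
spliced 5'UTR, CDS and 3'UTR are divided into 10, 20 and 20 windows, and
each cell of the resulting genes × 50 matrix holds the per-base peak
coverage of that window:

```
density(g, w) = covered spliced bases of window w / window size
```

Peaks are pre-processed to a confident set: fold enrichment > 2 and
FDR < 0.05 per replicate, at least 50% reciprocal overlap between two
replicates (`bedtools intersect -f 0.5` semantics), then merged.  The
window matrix is clustered with k-means (k = 5; kmeans++ restarts plus a
deterministic start at the five topology archetypes) and centroids are
labelled NMG / 5'MG / CMG / SMG / 3'MG by their dominant meta-region
(stop flank ≈ windows 28–32, ±100 nt around the stop codon).

For two stages the package reports the 5×5 transition table, per-group
**overlap ratios** (diagonal / reference-stage marginal), row-stochastic
**transition ratios** (fetal as reference), and the derived gene sets
**adult-loss 5'MGs** (fetal 5'MG → adult NMG) and **adult-gain SMGs**
(adult SMG not fetal SMG).  Quantification: TPM = counts·10⁶ / (length ·
Σ counts/length); TMM scaling factors (30%/5% trims, geometric mean 1,
library size absorbed into the factor); m6A level = IP TPM / input TPM;
differential genes at p < 0.05 and |log2FC| > 1 via an exact conditional
binomial rate test.  Statistics: tissue-specificity tau, pooled
two-proportion z-test (z² = χ² on 2×2), Pearson χ², two-sided Fisher's
exact test, odds ratios with Haldane correction, Pearson correlation,
and BH-adjusted gene-set enrichment.

A fully synthetic, seed-reproducible data generator (GTF + narrowPeak +
count tables + tissue panel) plants topology classes, a 5×5 transition
matrix, a negative m6A-level/expression correlation and tissue-specific
expression, so the entire pipeline is testable against known truth.

## Worked example

```r
library(m6Atopo)

cfg <- synthetic_config(n_genes = 1000, seed = 42)
res <- run_all(cfg, "m6atopo_demo")

res$assignments$fetal
#> TopologyAssignment over 948 genes (seed 42):
#> NMG 5MG 3MG CMG SMG
#> 181 185 185 186 211

round(res$ratios, 3)          # transition ratios, fetal rows
#>       stage2
#> stage1   NMG   5MG   3MG   CMG   SMG
#>    NMG 0.597 0.077 0.122 0.105 0.099
#>    5MG 0.481 0.319 0.114 0.038 0.049
#>    3MG 0.103 0.076 0.595 0.124 0.103
#>    CMG 0.129 0.097 0.091 0.586 0.097
#>    SMG 0.128 0.133 0.114 0.100 0.526

length(res$sets$adult_loss_5MG)   # fetal 5'MGs that become adult NMGs
#> [1] 89

read.delim(res$files[["correlation"]])
#>   stage          r       pvalue   n
#> 1 fetal -0.5024822 2.606434e-50 767
#> 2 adult -0.5145946 2.604783e-47 681
```

Of 1000 simulated genes, 948 pass the length filters and are classified;
the fetal 5'MG row shows the planted developmental signature — 48% of
fetal 5'MGs lose their 5'UTR methylation entirely (become NMGs), the 89
genes in `adult_loss_5MG` — while the other groups keep ~60% of their
members.  The m6A level anticorrelates with expression (r ≈ −0.5) in
both stages, as planted.  All outputs are also written as TSV under the
output directory, byte-identical across runs with the same seed.

The same functions run on real data: `read_gtf()` on a GENCODE GTF,
`read_peaks()` on MACS2 narrowPeak files, `read_count_table()` on
featureCounts-style TSVs, then `classify()`, `cross_tab()` and friends.

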