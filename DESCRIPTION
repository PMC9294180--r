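Package: m6Atopo
Title: m6A Topology Classification and Developmental Transition Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies protein-coding genes into five N6-methyladenosine
    (m6A) topology groups (NMG, 5'MG, 3'MG, CMG, SMG) from MeRIP-seq peak
    data by binning peak density into a 50-window metatranscript profile
    (10 windows over the 5'UTR, 20 over the CDS, 20 over the 3'UTR) and
    k-means clustering. Quantifies m6A levels (IP/input TPM) and expression
    (TPM, TMM), applies the differential expression/methylation criteria,
    and measures m6A topological transitions between two developmental
    stages (overlap ratios, transition ratios, adult-loss 5'MG and
    adult-gain SMG gene sets). Ships the statistical toolkit used
    throughout (tissue-specificity tau, two-proportion z-test, chi-square,
    two-sided Fisher's exact test, odds ratios, Pearson correlation,
    BH-adjusted gene-set enrichment) and a seed-reproducible synthetic-data
    generator (GTF, narrowPeak, count tables, tissue panel) with planted
    topology groups and transitions so every pipeline stage is verifiable
    against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    graphics,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
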