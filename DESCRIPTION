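Package: ccscan
Title: Case/Control Genome Scans for Selection and Autozygosity in Small Cohorts
Version: 0.1.0
Authors@R:
    person("Island", "Genomics", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for case/control genome scans in small,
    structured wildlife cohorts: genotype and site filtration of biallelic
    SNVs (depth, genotype quality, call rate, minor allele frequency),
    KING-robust kinship with exact maximum-unrelated-subset selection,
    genotypic linkage disequilibrium pruning and decay curves, sliding-window
    nucleotide diversity, Weir-Cockerham FST and Tajima's D with z-score
    outlier intersection, per-SNV allelic differentiation with gene and
    transcription-factor-binding-site annotation, sliding-window runs of
    homozygosity with FROH and cohort sharing tracks, and PCA on pruned
    neutral loci. Includes a synthetic two-island case/control cohort
    generator with known truth so every stage is testable without external
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    data.table,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
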