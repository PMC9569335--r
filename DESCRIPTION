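Package: epienrich
Title: Enrichment of GWAS Risk Variants at Epigenetically Active Regulatory Elements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether genetic risk variants from genome-wide
    association studies concentrate at epigenetically active regulatory
    elements in specific tissues and immune cell states. Implements a
    stratified LD-score regression engine with block-jackknife standard
    errors, conditional models and coefficient-difference tests; a
    specificity-rank enrichment statistic for peak-by-cell-state signal
    matrices with a discrete-uniform null; distance-based clumping of
    summary statistics to independent risk loci; LD expansion of lead
    variants against a reference panel; cross-disorder sharing and
    discordance summaries with exact small-sample Spearman correlation; and
    hypergeometric over-representation analysis with peak-to-gene
    assignment. A synthetic-data module generates LD-block-structured
    genotype panels, summary statistics with planted per-annotation
    heritability, and peak matrices with planted cell-state specificity, so
    the whole pipeline is testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    rtracklayer,
    limma,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'epienrich-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'annotations.R'
    'cheers.R'
    'clumping.R'
    'comparisons.R'
    'config.R'
    'io.R'
    'pathways.R'
    'sldsc.R'
    'synthetic-peaks.R'
    'synthetic-genotypes.R'
    'pipeline.R'
    'experiments.R'
    'ldscores.R'
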