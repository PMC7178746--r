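Package: danorm
Title: Normalization-Aware Differential Chromatin Accessibility Analysis for ATAC-seq
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for differential chromatin accessibility (DA) analysis of
    paired-end ATAC-seq data with explicit control over count normalization.
    Implements fragment-level preprocessing (Tn5 insertion-site coordinate
    shift, minimal-fragment conversion, blacklist filtering), region definition
    by ENCODE-style naive-overlap consensus peaks or de novo sliding windows
    with local-background enrichment, library molecular-complexity estimation
    from duplicate-frequency histograms with stochastic subsampling to
    equalized complexity, fragment counting over regions and genomic bins, six
    interchangeable normalization strategies (library size, reads in peaks,
    trimmed mean of M-values from large bins, abundance-dependent loess
    offsets, log2-CPM, quantile), an empirical-Bayes moderated-t testing
    engine with mean-variance observation weights plus a two-group negative
    binomial exact test, and a diagnostic layer (MA trends, FDR calibration,
    promoter annotation, precision-recall against expression, hypergeometric
    enrichment) for comparing how normalization choice changes DA calls.
    Includes negative-binomial count and fragment-library simulators that
    plant known differential regions, efficiency biases and complexity
    differences for method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    edgeR
Config/testthat/edition: 3
biocViews: Epigenetics, ATACSeq, DifferentialPeakCalling, Normalization,
    Sequencing, Coverage
RoxygenNote: 7.3.3
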