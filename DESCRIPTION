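Package: rnadecay
Title: Ex Vivo RNA Degradation Modelling and RIN-Aware Expression Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify and correct the distortion that ex vivo RNA
    degradation introduces into RNA-seq experiments. Provides a ground-truth
    simulator of degradation time courses (gene-specific first-order decay,
    RNA Integrity Number tied to degradation state, constant-mass exogenous
    spike-in, negative-binomial sequencing noise), per-gene decay-rate
    estimation from log-linear fits with Storey q-value classification of
    fast and slow degraders, RIN-aware differential expression under three
    strategies (negative-binomial GLM, GLM with RIN covariate, and linear
    models on RIN-residualized expression), and sample-level diagnostics
    (PCA with covariate association, Spearman correlation clustering,
    library-complexity metrics, and gene presence/absence over a time
    course). Normalization utilities cover read subsampling, exon-union
    gene models, RPKM, quantile normalization and TMM scaling factors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Matrix,
    edgeR,
    limma,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse,
    yaml
Config/testthat/edition: 3
biocViews: RNASeq, GeneExpression, Normalization, DifferentialExpression,
    QualityControl, Software
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'normalize.R'
    'decay.R'
    'de.R'
    'structure.R'
    'io.R'
    'simulate.R'
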