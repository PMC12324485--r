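Package: tdmdkit
Title: Discovery and Characterization of Target-Directed miRNA Degradation Triggers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis toolkit for discovering and characterizing
    target-directed miRNA degradation (TDMD) trigger RNAs from chimeric
    CLIP-style sequencing data. Provides hybrid (miRNA-target chimera) read
    calling with UMI-aware preprocessing, per-total-hybrid normalization and
    binding-site clustering; genotype-enrichment ranking of candidate trigger
    interactions with family-level aggregation; intermolecular miRNA:target
    duplex prediction by dynamic programming and pairing-architecture
    classification (seed, supplemental, 3' end); isomiR 3' trimming/tailing
    decomposition and genotype comparison; small RNA-seq count normalization
    by normalizer class with permutation-based fold-change inference,
    guide/passenger decay-level calls and mutant pathway-congruence
    classification; and absolute-quantification stoichiometry (qPCR standard
    curves, excess-molecule and molecules-degraded-per-trigger arithmetic,
    stage deconvolution, smFISH spot-to-molecule binning). A synthetic-data
    module generates complete experiments with planted ground truth so the
    whole pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    BiocGenerics,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
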