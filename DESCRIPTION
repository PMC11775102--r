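Package: chromdyn
Title: Chromatin-State Dynamics and Environment Analysis for Germ Cell Epigenomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative analysis of histone-mark chromatin states and gene
    regulation across male germ cell differentiation stages. Provides a
    Bernoulli-emission hidden Markov model for chromatin-state segmentation
    from binarized histone-mark tracks (200 bp bins), peak annotation and
    cross-stage peak dynamics classification, enhancer classification with
    gene linking within 100 kb, promoter chromatin-environment assignment,
    spike-in-anchored differential expression (control-gene unwanted-variation
    removal and a negative-binomial fold-change-threshold test), heterologous
    spike-in scaling for CUT&Tag signal, region-overlap permutation
    association tests, and a synthetic-data generator with planted ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
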