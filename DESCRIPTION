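Package: itbregnet
Title: Conserved Regulatory Network Inference from Single-Nucleus Chromatin Accessibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers a conserved transcription-factor-family to target-gene
    regulatory network for an invasive trophoblast cell population from
    cell-labeled single-nucleus ATAC-seq fragment counts. Provides
    depth-adjusted logistic-regression differential accessibility testing,
    TF-IDF normalization and gene-activity scoring, peak-to-gene association
    with over-representation analysis, cross-species peak conservation via a
    simplified interval mapping, PWM motif scanning with exact score-threshold
    computation and GC/length-matched backgrounds, TF-family co-occurrence
    statistics, bipartite network assembly, and a synthetic-data generator
    with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    igraph,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
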