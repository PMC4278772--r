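Package: patseq
Title: Poly(A) Tag Sequencing Analysis of Alternative Polyadenylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing poly(A) tag sequencing (PAT-seq) experiments:
    simulation of multiplexed 3'-end tag libraries with known ground truth,
    demultiplexing and oligo-dT/adapter trimming, construction of an extended
    reverse-complemented 3'-UTR mapping database, deterministic k-mer seed
    alignment of tags with SAM export, per-gene poly(A)-site profiling and a
    bounded [0,1] profile-difference metric with cumulative-curve comparison,
    and poly(A)-tag digital gene expression (tags-per-million normalization,
    expression filtering, pairwise log2 ratios, a multi-ratio fold-change
    screen, Wilcoxon rank-sum functional-bin enrichment, and a weighted
    proportions test for replicated count data).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    methods,
    purrr,
    Rcpp,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    Rsamtools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
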