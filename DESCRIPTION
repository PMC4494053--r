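Package: trpprof
Title: Profile-Based Subfamily Classification, Repeat Counting and
    Specificity Analysis for TRP Channel Superfamilies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds position-specific profile models of ion-channel
    subfamilies from multiple sequence alignments, scores proteins by local
    Viterbi log-odds with Gumbel-calibrated E-values, runs an iterative
    inclusion search, partitions homolog sets into subfamilies by an
    encoding-cost agglomerative criterion, classifies proteins by a
    competitive best-hit rule with unspecific-model exclusion, counts tandem
    ankyrin repeats by greedy non-overlapping profile tiling, collapses
    redundant sequence sets by greedy centroid clustering at an identity
    threshold, and identifies mechanism-specific alignment positions with a
    physico-chemical conservation score, a two-group multi-Relief statistic,
    a permutation z-test and a complete-disjunctness filter. Includes a
    seeded synthetic-superfamily generator so every stage is testable
    without external databases.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
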