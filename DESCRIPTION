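Package: hlabench
Title: Evaluation and Majority-Vote Consensus for HLA Genotyping Tools
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tidy toolkit for benchmarking HLA genotyping callers against
    PCR-derived gold standards and for combining them into a majority-vote
    consensus ("metaclassifier"). Implements IPD-IMGT G-group allele
    normalization and second-field trimming, the per-allele accuracy metric
    with its homozygosity and no-call rules, pairwise tool concordance,
    greedy forward selection of a minimal complementary tool subset,
    sample-size-weighted aggregation of population allele-frequency studies
    with observed-vs-expected Pearson correlation, and coverage statistics
    linking read depth to call correctness (rank-sum test, logistic model,
    subsampling arithmetic and minimum-depth interpolation). A synthetic
    Hardy-Weinberg data generator emulates tool call tables so every stage
    is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
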