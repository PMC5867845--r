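Package: mitohet
Title: Deep-Coverage Mitochondrial Heteroplasmy Calling, Classification and
    Error Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-native pipeline for analysing low-frequency point
    heteroplasmy in deep-coverage human mitochondrial DNA sequencing data.
    Converts per-position allele-count tables into minor-variant calls under
    a configurable filter stack (analytical and reporting thresholds,
    minimum variant reads, total coverage, strand-balance and quality-score
    balance), classifies heteroplasmic sites across mother-child pairs
    sampled in buccal and blood tissue as shared, differentiating or random,
    annotates sites against the mitochondrial gene map and vertebrate
    mitochondrial genetic code, profiles per-position substitution error
    with motif context, computes cohort summary statistics with Welch
    two-sample comparisons, and ships a germline-bottleneck drift simulator
    that emits pileups with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
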