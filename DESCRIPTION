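Package: omicwalk
Title: Multi-Omic Aberration Integration and Network Propagation for
    Cancer Gene Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for integrating paired tumor/normal multi-omic data
    (expression, copy number, promoter methylation, somatic mutation) in the
    style of TCGA colorectal cancer studies. Calls per-layer aberrations with
    FDR and fold-change gates, forms sign-consistent candidate gene groups
    with hypergeometric overlap statistics, propagates seed scores over a
    merged gene network by random walk with restart with a node-label
    permutation null, and evaluates candidate signatures by Cox-derived
    linear risk scores with median-split Kaplan-Meier, cross-validation and
    fixed/random-effect meta-analysis. Ships a synthetic multi-omic cohort
    generator with known ground truth so the full pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    igraph,
    IRanges,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
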