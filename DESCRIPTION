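Package: majunction
Title: Junction Micro-Homology and Mutation-Rate Analysis for Mutation
    Accumulation Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising structural variants that accumulate in
    mutation accumulation (MA) lines, with an emphasis on the mutational
    footprint of theta-mediated end joining (TMEJ): consolidation and
    filtering of multi-caller variant calls, shift-invariant scoring of
    micro-homology at deletion and tandem-duplication junctions,
    classification of junction insertions as templated or non-templated,
    a Monte-Carlo random-deletion null model for the expected micro-homology
    fraction, per-generation mutation-rate estimation with genotype
    comparisons and the six-class base-substitution spectrum, and a seeded
    simulator that generates genomes, MA lines, truth sets and noisy caller
    records so every stage of the pipeline can be tested end to end.
License: MIT + file LICENSE
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
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
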