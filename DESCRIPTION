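Package: fracprof
Title: Size-Fractionated Metagenome Profiling and Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative analysis of size-fractionated shotgun metagenomes
    from annotated read tables: tiered percent-identity filtering of peptide
    hits, relative-abundance matrices with explicit denominators, two-proportion
    significance tests, effective-genome-size and genome-equivalent
    normalization of functional categories from single-copy marker density,
    D-score differential abundance between size fractions, fragment
    recruitment-plot coverage statistics, SSU rRNA dereplication and
    alignment-depth OTU estimation, and hierarchical clustering and PCA of
    family abundance profiles. Includes a synthetic-community generator that
    emulates post-annotation hit tables with known ground truth, so every
    stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    jsonlite,
    methods,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
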