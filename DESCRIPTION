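Package: colonybin
Title: Differential-Coverage Binning of Single Cyanobacterial Colony Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recovers draft population genomes from metagenomes of single
    cyanobacterial (Microcystis) colonies by differential-coverage binning of
    assembled scaffolds across colony samples, with standardization of the GC
    bias introduced by multiple displacement amplification (MDA),
    composition-based (tetranucleotide frequency) refinement of mixed bins,
    and single-copy marker-gene completeness accounting. Includes a synthetic
    colony-community simulator with planted ground truth (differential
    abundance, MDA GC bias, genome-specific k-mer composition, planted
    markers), a native implementation of sliding-window read trimming, and
    hierarchical clustering of genus-level abundance profiles for replicate
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
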