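Package: proipr
Title: Analysis of PRO-IP-seq Nascent Transcription Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Downstream analysis of PRO-IP-seq experiments, which map engaged
    RNA polymerase II complexes at nucleotide resolution after selecting
    transcription complexes by their CTD modification state. Provides
    demultiplexing of inline-barcoded reads and UMI-based duplicate collapsing,
    spike-in genome masking and counting, strand-specific single-nucleotide
    5'- and 3'-end count tracks, spike-in anchored nf-cRPM normalization,
    transcription start nucleotide and pause nucleotide calling with early and
    late pause classification, per-nucleotide log2 phosphorylation ratio
    tracks, anchored composite (metagene) profiles, and a ground-truthed
    synthetic data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    withr,
    yaml,
    stats,
    utils,
    methods,
    graphics,
    GenomicRanges,
    IRanges,
    Biostrings,
    rtracklayer,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
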