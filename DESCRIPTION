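Package: ribopause
Title: Differential Ribosome Pausing, Spike-In Silencing, and Barcode
    Screen Analysis for Aneuploid Yeast
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for codon-level analysis of
    ribosome profiling data in euploid versus aneuploid yeast entering
    quiescence. Converts aligned footprint 5' ends to P-site codon counts,
    normalizes per-codon occupancy to the gene body, calls differentially
    paused codons with Fisher's exact test and Benjamini-Hochberg
    correction, scores flanking amino-acid enrichment at stall sites
    against the proteome, summarizes chromosome dosage, performs spike-in
    slope normalization with a transcriptome-silencing gene-selection
    rule, and implements a pooled barcode-screen hit-selection cascade
    with native TMM normalization. Ships a synthetic-data generator
    (genomes, Dirichlet-multinomial footprints, spike-in RNA counts,
    negative-binomial screen barcodes) with ground-truth records for
    recovery testing.
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
    GenomicRanges,
    ggplot2,
    IRanges,
    limma,
    methods,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    edgeR,
    jsonlite,
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
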