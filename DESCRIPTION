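Package: simbench
Title: Truth-Aware RNA-Seq Read Simulation and Qualitative Pipeline Benchmarking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates RNA-seq experiments from a reference genome and transcript
    annotations with injected single-nucleotide variants, short indels and gene
    fusions; lifts simulated read alignments back to original reference
    coordinates and encodes the ground truth (alignments and sequencing-error
    positions) in the read names; and evaluates pipeline predictions
    (alignments, splice junctions, SNVs, indels, fusions) against the recorded
    truth with interval-tree matching, reporting true/false positive and false
    negative counts together with precision, recall and F-score.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    utils,
    vcfR,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
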