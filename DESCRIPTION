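Package: switchJunctions
Title: Calling and Analysis of Immunoglobulin Class-Switch Recombination
    Junctions from Amplicon Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies class-switch recombination (CSR) junctions in
    amplicon sequencing reads by sequential local alignment against a donor
    switch region (Smu) and downstream acceptor switch regions, resolves the
    breakpoint pair under an explicit donor-maximal convention, classifies
    the repair structure of each joint (blunt, microhomology, untemplated
    insertion), and assembles identical junctions into clusters. Provides
    degenerate-motif (WRCY) scanning of switch-region references with
    nearest-distance queries, a random-break reference distribution, an
    approximate permutation test on breakpoint-to-hotspot distances, and a
    chi-square comparison of junction-structure composition. A synthetic
    junction-read generator with a ground-truth table makes the whole
    pipeline verifiable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    withr,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
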