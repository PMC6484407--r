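Package: polwave
Title: Transcription Elongation Rates and Kinetic Coupling from
    DRB-Release Nascent RNA Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Per-gene RNA polymerase II elongation-rate inference from
    DRB-release nascent-RNA time courses, in both the sequencing variant
    (binned 4sU-DRB-seq coverage, two-segment Poisson wave-front
    detection, two-point or regression rate estimation) and the qPCR
    variant (exon-intron junction detection times). Downstream
    kinetic-coupling statistics: percent-spliced-in (PSI) differential
    splicing with a beta-posterior dPSI test, exon/intron length
    comparisons, motif RNA maps with permutation significance,
    dPSI-versus-expression regression, gene-length sliding-window
    downregulation curves, and gene-set overlap tests. A synthetic-data
    generator emulates the full experimental design so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
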