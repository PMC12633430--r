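Package: gameteMEI
Title: Single-Read Detection and Characterization of De Novo Alu Insertions
    in Gamete Long Reads
Version: 0.1.0
Authors@R:
    person("gameteMEI", "Developers", email = "gametemei@example.org",
           role = c("aut", "cre"))
Description: Toolkit for direct, single-read discovery of de novo mobile
    element insertions (MEIs) in long-read sequencing of gametes. Provides a
    read-level insertion simulator with truth tracking, a benchmark
    classifier for precision/recall against spiked truth, annotation of
    insertion candidates against a repeat consensus library and genomic
    features, a read-evidence confidence score with an ordered filter
    cascade, extraction of target-primed reverse transcription hallmarks
    (target site duplications, poly(A) tails, orientation, 5' truncation,
    breakpoint context), and closed-form gamete-sampling and per-gamete
    mutation-rate models with age regression and outlier testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    IRanges,
    Rsamtools,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
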