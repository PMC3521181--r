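Package: sblpal
Title: Simulation and Analysis of Palindrome-Induced Failure in
    Sequencing-by-Ligation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study how perfect DNA palindromes defeat
    sequencing-by-ligation (SOLiD-style) chemistry. Provides a maximal
    reverse-complement palindrome scanner with FASTA input and BED output, a
    model of a palindromic ditag construct and its MmeI (type IIS) digestion
    into near-homogeneous template fragments, a read simulator implementing
    the five-primer two-base interrogation schedule with a hairpin-blocking
    failure model (random-base emission at the instrument floor quality value
    inside the blocked window), read quality-control filters, anchored tag
    classification with library statistics, and per-position quality and
    good/best bead-ratio profiling.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
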