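Package: RIPforge
Title: Design and Analysis of Interspersed DNA Homology for Repeat-Induced
    Point Mutation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how Neurospora crassa recognises DNA homology
    during repeat-induced point mutation (RIP). Designs test sequences that
    realise interspersed-homology patterns (XH-YN_Z) against a fixed reference,
    composes full repeat cassettes with perfect-homology blocks, junction
    inserts and interruptions, performs targeted single-nucleotide triplet
    edits (e.g. removal of GAC units), censuses the canonical base-pair
    triplets contained in homologous units, calls C-to-T and G-to-A RIP
    mutations in spore contigs, summarises them as per-spore counts and
    per-site mutation profiles, and compares constructs with two-sample
    Kolmogorov-Smirnov tests and per-site Pearson correlation. A stochastic
    spore simulator with planted mutations makes the whole pipeline runnable
    and testable without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
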