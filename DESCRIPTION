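Package: trapscreen
Title: Insertion-Site Deconvolution for Gene-Trap Transposon Screens
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Deconvolutes transposon integration sites from non-restrictive
    linear amplification PCR (nrLAM-PCR) junction reads produced by
    Tol2 gene-trap screens, as used in split-GFP PARylation biosensor
    screening. Trims the transposon junction tag, maps genomic flanks,
    merges alignments into cross-sample master blocks, removes PCR
    duplicates by unique fragment length, applies the screen's filter
    ledger (read-depth, read-stack orientation, negative-control
    subtraction, genic/fusion viability), and annotates surviving sites
    with splice-acceptor reading-frame predictions and N-terminal
    truncation lengths. Includes a synthetic-data generator that emulates
    the screen's read structure (triplicate replicate reactions, PCR
    duplicates, decoy insertions, shared control sites) so every stage is
    verifiable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
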