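Package: pb10x
Title: Plate-Based 10X-Compatible 5' scRNA-seq Protocol Toolkit
Version: 0.1.0
Authors@R: person("NXT", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computational companion to a plate-based, 10X-compatible 5'
    single-cell RNA-seq protocol in which the cell barcode is carried by the
    template-switching oligonucleotide (TSO). Provides Levenshtein-constrained
    selection of well-specific barcodes from a 10X whitelist and assembly of
    the barcoded TSO oligos; a seeded read simulator reproducing the protocol
    read geometry (26 nt R1 = 16 nt barcode + 9 nt UMI + first spacer base,
    90 nt R2) with injectable TSO-concatemer and strand-invasion artifacts;
    read-1 demultiplexing with whitelist barcode correction and pool
    assignment; artifact QC (junction-literal concatemer detection, fuzzy
    matching of the UMI-spacer-GGG pattern against upstream genomic context);
    and benchmarking statistics (sequencing saturation, dropout ratios,
    per-cell QC, paired TCR recovery from AIRR tables).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
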