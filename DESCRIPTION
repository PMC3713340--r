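Package: beldyad
Title: Strand-Aware Discovery of Tandem TGAC Cis-Elements in Promoter Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Finds tandem TGAC-core (BEL1/KNOX-type binding) cis-elements in
    upstream regulatory sequences. Cores (TGAC, extended TTGAC; GTCA/GTCAA on
    the opposite strand) are located on both strands, paired into dyad elements
    under a linker-length constraint, classified by relative strand orientation
    (HtH, HtT, TtH, TtT) and reported with their distance upstream of a TSS or
    start-codon anchor. Includes strand-aware upstream-window extraction from
    FASTA/GFF3, an exact dynamic-programming background model for the
    probability of a chance dyad in a random window, generators for core-free
    synthetic promoters with embedded elements and simulated qPCR Ct tables,
    and a comparative-threshold-cycle (2^-ddCt) induction analysis with
    replicate significance testing and linker-length correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
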