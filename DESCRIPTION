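Package: mirscout
Title: Stringent miRNA Discovery from Small RNA Sequencing Read Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovers candidate microRNA precursor loci from small RNA
    sequencing libraries with an emphasis on controlling false positives.
    Collapsed reads are mapped to a genome without mismatches, hairpin
    candidates with guide/passenger duplex evidence are collected in
    46-80 nt windows, each candidate is scored on ten biogenesis-signature
    parameters (5' end heterogeneity, duplex 3' overhangs, duplex and
    flanking-region folding energy, sequence and structure entropy,
    non-templated A/U tailing and multimapping contamination), and
    per-parameter cutoffs are calibrated against annotated miRNAs until the
    estimated false-positive rate of the prediction drops to a target level.
    A seeded synthetic-data generator produces toy genomes with planted
    miRNA and decoy loci so the whole pipeline can be exercised offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    Rcpp,
    rtracklayer,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
SystemRequirements: ViennaRNA (RNAfold, RNAduplex) is used as the folding
    backend when available; a built-in dynamic-programming fallback is
    bundled.
Config/testthat/edition: 3
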