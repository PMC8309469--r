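Package: promoterscan
Title: Promoter Cis-Regulatory Hexamer Scanning Against First-Order Markov Null Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scans genomes and 2000-bp upstream promoter regions for degenerate
    hexamer cis-regulatory elements (W-, A-, T-, C- and G-boxes) on both strands,
    estimates mononucleotide and first-order dinucleotide composition models from
    whole genomes or GC-stratified fragment sets, computes the stochastic
    (first-order Markov chain) expectation for motif occurrence per window, and
    compares observed counts to that expectation. Builds comparative
    promoter-annotation tables for ortholog families, summarizes intron-exon
    architecture of gene cohorts, and generates seeded synthetic genomes,
    promoters and annotations with planted motifs so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
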