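Package: finchmir
Title: Small-RNA Sequencing Analysis of a Songbird microRNA Repertoire
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for annotating and analysing a microRNA
    repertoire from multiplexed small-RNA sequencing libraries, modelled on
    the zebra finch (Taeniopygia guttata) multi-tissue, two-sex study design.
    Covers demultiplexing by pentamer barcode and adapter trimming, exact
    genome mapping and small-RNA class partitioning, hairpin precursor
    detection by maximum base-pairing dynamic programming, novel miRNA
    calling from read stacks (hairpin, read support, star strand, 5' end
    precision), conservation tiering and genomic clustering, isomiR and
    internal-substitution profiling with GGU-motif analysis, tissue-enriched
    and sex-biased (Z-linked dosage) expression calls, seed-match target
    prediction on 3' UTRs, and Fisher-exact chromosomal target enrichment.
    A synthetic genome and read generator with a full truth table makes every
    stage testable without external sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    S4Vectors,
    methods,
    rtracklayer,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
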