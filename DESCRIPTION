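Package: srnablocks
Title: Proximity-Block Quantification and Discovery of Small RNAs
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tissue-survey pipeline for plant small-RNA sequencing data:
    read collapsing and abundance-ranked error correction, hierarchical
    alignment triage against structural-RNA and organellar decoys, proximity
    based block building with 1/k multi-mapper weighting, two-proportion
    (difference-in-proportion) differential expression with Bonferroni
    control, hairpin-criteria prediction of novel microRNA loci, and
    functional classification of differentially expressed blocks into
    miRNA-like and siRNA-like classes. Ships a synthetic genome and library
    simulator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
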