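Package: mircert
Title: Validation and Annotation of Candidate microRNA Loci from Small RNA
    Read Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Certifies candidate microRNA loci from small RNA sequencing data
    using the structural and expression criteria developed for lineages, such
    as the brown algae, where miRNAs evolved independently of plants and
    animals. Collapsed sRNA reads are filtered and aligned exactly onto
    candidate hairpin precursors, precursors are folded with a deterministic
    base-pair maximization engine, and each locus is scored against four
    criteria: opposite-arm pairing of the mature miRNA, expression of the
    miRNA* partner, the 2-nt 3' overhang diagnostic of Dicer processing, and
    5' processing homogeneity. Rejected loci receive a diagnosis (no reads,
    dominant read outside the miRNA, invalid duplex), and loci embedded in
    extended palindromic regions are down-graded to weak candidates. Certified
    loci are annotated with genomic context, clusters, seed- and
    identity-based families, expression summaries, foldback lengths and
    cross-genome homology hits. A synthetic-data generator plants hairpin loci
    with known truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    digest,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    igraph,
    IRanges,
    purrr,
    Rcpp,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    knitr,
    optparse,
    Rsamtools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
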