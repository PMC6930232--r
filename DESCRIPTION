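Package: ripscan
Title: Retrotransposon Insertion Polymorphism Detection from Paired-End Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects retrotransposon insertion polymorphisms (RIPs) in
    resequenced plant cohorts from discordant paired-end read evidence.
    One mate of a pair is mapped to a family-labelled transposable-element
    (TE) reference, the other is anchored uniquely on the genome, anchors
    are tallied in fixed 10 kb windows, and windows supported by more than
    three read pairs are called as insertion loci. Downstream modules build
    the cohort presence/absence RIP matrix, compute per-group insertion
    frequencies and Venn partitions, per-family copy numbers, population
    structure through a genetic relationship matrix and its leading
    principal components, and genomic-context statistics (feature classes,
    distance to TSS, megabase density correlation, metagene profiles).
    A synthetic cohort generator with known insertion truth makes every
    stage testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    data.table,
    GenomicRanges,
    IRanges,
    jsonlite,
    Rcpp,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
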