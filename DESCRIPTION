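Package: plantSmallRNA
Title: Small RNA and Degradome Analysis for Plant miRNA Discovery
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for plant small-RNA sequencing and degradome
    (PARE) analysis. Cleans and collapses small-RNA libraries, partitions
    unique tags into ncRNA and genomic annotation categories, identifies
    known mature miRNAs by mismatch-tolerant matching, discovers novel
    miRNA hairpins from genome windows with a nearest-neighbor stacking
    folding engine and duplex (2-nt 3' overhang) criteria, performs TPM
    normalization and Student's t / Benjamini-Hochberg differential
    expression between lines, and calls miRNA cleavage targets from
    degradome tags with position-weighted complementarity scoring and
    abundance-based class 1/2/3 categorization. A seeded synthetic-data
    module generates genomes with planted hairpins, negative-binomial
    replicate libraries and degradome tags so that every stage has a
    ground-truth recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
biocViews: Sequencing, SmallRNA, GeneExpression, DifferentialExpression
RoxygenNote: 7.3.3
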