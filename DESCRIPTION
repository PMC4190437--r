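Package: mirIsland
Title: Coverage-Island Discovery of MicroRNAs and Negative-Binomial
    Differential Expression for Small RNA-Seq
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for miRNome discovery and differential expression from
    aligned small-RNA sequencing libraries. Candidate miRNA loci are
    detected as read-coverage islands, dual precursor windows are excised
    around each locus and folded with a built-in minimum-free-energy
    secondary-structure algorithm, hairpin candidates are annotated against
    known miRNAs or classified as novel by size, abundance and folding-energy
    filters, and per-locus counts are tested for differential expression
    between condition groups with a negative-binomial conditional exact test
    under median-of-ratios normalization, with Benjamini-Hochberg adjustment
    and between-class analysis ordination. A synthetic-data generator plants
    hairpin precursors and decoy loci in a toy genome and emits multi-library
    aligned reads with known negative-binomial count structure, so every
    stage of the pipeline can be validated against ground truth at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
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
    Rsamtools,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite,
    optparse
biocViews: Sequencing, SmallRNA, Transcriptomics, DifferentialExpression,
    Coverage, StructuralPrediction
Config/testthat/edition: 3
RoxygenNote: 7.3.3
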