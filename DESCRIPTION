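Package: segdupnet
Title: Segmental Duplication Networks and Reconstruction of Duplication
    Events
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds a network of duplicated genomic regions from pairwise
    segmental-duplication alignments, reconstructs primary duplication
    events with a shared-neighbor-weighted minimum spanning forest, and
    validates the reconstruction against a preferential-copying network
    growth simulator extended with sequence-identity decay and non-allelic
    gene conversion. Downstream analyses include comparisons of duplicated
    regions against shuffled genomic backgrounds, repeat profiles around
    duplication breakpoints, permutation-calibrated random-forest feature
    importance, partial Spearman correlations, and nonnegative matrix
    factorization of windowed duplication features into duplication
    signatures. A forward simulator of duplications on a synthetic genome
    provides fully self-contained test data with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    igraph,
    randomForest,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Network, GraphAndNetwork, Genetics, Software
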