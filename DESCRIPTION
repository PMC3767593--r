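Package: xistkit
Title: Assembly and Epigenetic Characterisation of an XIST-Like lncRNA Locus
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to define a long non-coding RNA gene of the XIST type from
    first principles: homology-guided candidate-region selection on a genomic
    scaffold, exon-intron model assembly from spliced amplicons with GT/AG
    splice-site validation and N-gap filling, transcript start and termination
    site calling from RACE-style clone ends, tandem-repeat consensus analysis
    with base-pair-maximising monomer folding, promoter CpG enumeration and
    clone-level bisulfite methylation quantification, and short-read coverage
    verification of sex-specific expression. A synthetic-locus generator with a
    full ground-truth table makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    withr,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Genetics, Epigenetics, Sequencing, Alignment, GenePrediction
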