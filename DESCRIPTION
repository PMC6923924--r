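Package: riboem
Title: Isoform-Level Ribosome Footprint Allocation with a Codon-Context Shape Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates isoform-level ribosome abundance and codon-resolution
    ribosome occupancy from ribosome profiling (Ribo-seq) data alone, without
    RNA-seq guidance. Multi-mapped footprints are allocated iteratively in
    proportion to CDS-length-normalized ribosome abundance, optionally combined
    with an "instructive shape" predicted by a codon-context convolutional
    network trained on the data being processed. Includes a ribosome
    flow model based synthetic data generator with full ground truth,
    an exact transcriptome multi-mapper and SAM/BAM import, and downstream
    translation statistics: translation efficiency, ribosomal stalling
    detection, and the Codon Residence Index (CRI) with between-condition
    comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    Rcpp,
    Biostrings,
    Rsamtools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
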