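Package: coevclade
Title: Clade-Wise Coevolution Integration for Protein-Protein Interaction Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds per-clade paired multiple sequence alignments from
    single-protein alignments and ortholog tables, scores inter-protein
    residue coevolution with mean-field direct coupling analysis (DCA),
    integrates the top per-clade signals through a random-forest classifier
    with explicit missing-clade imputation, and re-ranks predictions with
    protein-level average product correction. Ships a Potts-model
    multi-clade alignment simulator with planted couplings so the whole
    pipeline is testable end to end without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    ranger,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
NeedsCompilation: yes
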