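Package: phylotroph
Title: Codon-Model Selection Tests and Molecular Phyloecology of Ancestral Diets
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects positive selection in protein-coding genes along designated
    ancestral branches of a species tree using Goldman-Yang codon models
    (one-ratio and two-ratio branch models, the four-class branch-site model
    with likelihood ratio tests and empirical-Bayes identification of selected
    sites) and quantifies selection-intensity shifts between branch partitions
    through an exponent on the omega distribution (RELAX-style k test).
    Per-gene results are aggregated over digestion-and-absorption pathway
    catalogs into nutrient profiles and a rule-based ancestral-diet call with a
    marker-gene evidence trail. A codon sequence simulator with the same model
    structure supports calibration, power analysis, and end-to-end scenario
    studies without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    Matrix
Config/testthat/edition: 3
RoxygenNote: 7.3.3
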