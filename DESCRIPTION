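Package: pinnevo
Title: Lineage-Specific Positive Selection and Site-Wise Likelihood Support
    for Marine Mammal Comparative Genomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects genes under lineage-specific positive selection with
    Goldman-Yang codon substitution models (one-ratio, branch, and branch-site
    model A with F3X4 codon frequencies), likelihood-ratio tests with
    Bonferroni correction, and Bayes empirical Bayes site posteriors.
    Computes site-wise log-likelihood support (deltaSSLS) between competing
    topologies under the JTT amino-acid model, reconstructs joint ancestral
    protein sequences, classifies clade-unique and parallel amino-acid
    substitutions, and intersects the resulting gene sets into a candidate
    list of rapidly evolving genes carrying clade-unique substitutions.
    Includes a codon-alignment simulator over a 12-taxon mammal phylogeny
    with configurable selection regimes and planted substitutions, so every
    stage of the analysis can be validated on data with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape (>= 5.0),
    phangorn (>= 2.10),
    Rcpp,
    jsonlite,
    graphics,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr,
    optparse
Config/testthat/edition: 3
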