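Package: phenoscreen
Title: Phenotypic Virtual Screening with Bagged Multi-Target Predictive Clustering Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ligand-based virtual screening for dual-reporter phenotypic
    assays of myofibroblast activation. Compounds are described by extended
    connectivity fingerprints computed from SMILES, and a bagging ensemble of
    multi-target predictive clustering trees jointly predicts alpha-smooth
    muscle actin (RFP) and collagen (EGFP) fold-over-control intensities.
    The package estimates predictive performance by k-fold cross-validated
    mean absolute error, scores per-prediction reliability as the spread of
    individual tree predictions, screens candidate libraries for predicted
    activity, removes training-set compounds, groups surviving hits by
    Tanimoto similarity to a reference drug panel, and ships a synthetic
    screen generator so the whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    tibble,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
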