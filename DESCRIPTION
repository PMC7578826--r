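Package: cmpanel
Title: Biomarker Panel Selection and Case Subtyping for Circulating
    Microparticle Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for case-control biomarker discovery from circulating
    microparticle (CMP) proteomic abundance data. Implements quantitative
    preprocessing (total-ion-current and reference-median normalisation,
    within-group coefficient-of-variation filtering, correlation-based
    redundancy pruning, interaction-network degree filtering), a bivariate
    logistic screen with uncapped Bonferroni correction, an iterated
    cross-validated panel-selection engine (outer 80/20 resampling, ensemble
    feature ranking, all-subsets logistic model search with inner five-fold
    cross-validation selected by AUC), a permuted-label null for panel
    validation, and case-only subtype discovery by silhouette-selected
    K-means with differential-expression and clinical-association
    statistics. A seeded synthetic-cohort generator with planted signal
    proteins, correlated protein blocks and latent case subtypes makes the
    whole workflow testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    cluster,
    graphics,
    grDevices,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
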