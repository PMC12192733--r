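Package: qsarens
Title: QSAR Ensemble Modelling and Virtual Screening for Enzyme Inhibition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for building and deploying QSAR
    (quantitative structure-activity relationship) models for enzyme-inhibition
    screening. Covers bioactivity curation from SMILES + IC50 tables
    (salt and water stripping, duplicate resolution by geometric mean, 50 nM
    activity labelling, pIC50 transform), molecular descriptor computation via
    a pluggable Open Babel/ChemmineR provider, unsupervised feature reduction
    (constant/infinite removal, correlation filtering, kNN imputation,
    standard scaling), k-means cluster-stratified splitting, genetic-algorithm
    wrapper feature selection with penalized cross-validated fitness,
    grid-search tuning of random forest, extra trees and AdaBoost learners,
    hard- and weighted soft-voting ensembles, kNN-density applicability
    domains with an ensemble coverage rule, batch prediction from SMILES
    lists, and single-point fluorogenic assay analysis with hit calling and
    confusion-matrix scoring.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    withr,
    jsonlite,
    ranger,
    rpart,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
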