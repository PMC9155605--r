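Package: herbsig
Title: Graph-Based Molecular Signatures for Herbicide Activity and
    Toxicity Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes graph-based signatures (cutoff scanning matrices) over
    pharmacophore-labelled molecular graphs parsed from SMILES, together with
    a complementary physicochemical descriptor block and herbicide-likeness
    property windows.  Provides a model laboratory for training and
    evaluating random-forest classifiers and regressors of herbicidal
    activity and toxicity endpoints under stratified cross-validation and
    blind tests, an exhaustive connected-substructure miner for identifying
    fragments enriched in active compound classes, and a synthetic
    structure-activity data generator with planted, recoverable ground
    truth.  A command-line interface ties the pieces into a
    featurize/train/predict/mine workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineOB,
    ChemmineR,
    Rcpp,
    igraph,
    jsonlite,
    randomForest,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    withr,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
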