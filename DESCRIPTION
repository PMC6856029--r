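Package: metabench
Title: Benchmarking Binary Classifiers on Metabolomics Feature Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A standardised workflow for building, optimising, and evaluating
    eight archetypal machine-learning classifiers (PLS-DA, principal-component
    regression and logistic regression, linear and radial-basis-function kernel
    support vector machines, random forests, and linear and sigmoidal two-layer
    neural networks) on binary-outcome metabolomics feature tables. Implements
    the two-table tidy data format (a samples-by-metabolites 'Data' table linked
    to a metabolite 'Peak' annotation table), stratified train/test splitting,
    Monte-Carlo cross-validated hyperparameter optimisation with Pareto-front
    knee-point selection, ROC/AUC evaluation, and out-of-bag bootstrap ROC
    confidence bands, together with a synthetic feature-table generator with
    low-rank inter-metabolite covariance for testing the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    readxl,
    pROC,
    optparse,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
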