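Package: esknn
Title: Ensemble of Subsets of k-Nearest-Neighbour Classifiers
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-stage ensemble classifier for binary classification designed
    to be robust to non-informative features. Base k-nearest-neighbour
    learners are trained on random feature subsets of bootstrap samples,
    ranked by their out-of-bag accuracy, and then combined greedily while the
    Brier score of the averaged-probability ensemble on a held-out validation
    set strictly decreases. Ships the classical kNN-family comparators
    (bagged kNN, random-subspace kNN, multiple-feature-subset kNN) with
    optional random-forest and support-vector-machine adapters, two
    Monte-Carlo simulation models with appendable noise features, and a
    seeded benchmarking harness with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: Rcpp, jsonlite, stats, utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), randomForest, kernlab
Config/testthat/edition: 3
RoxygenNote: 7.3.3
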