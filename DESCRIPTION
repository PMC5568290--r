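Package: lupusnlp
Title: Clinical-Note Phenotyping of Systemic Lupus Erythematosus with
    Classical Classifiers and Word2Vec Bayesian Inversion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, reproducible pipeline for phenotyping systemic
    lupus erythematosus (SLE) from free-text clinical notes. Generates
    synthetic electronic-health-record corpora with ACR/SLICC rule-based
    ground truth (class-correlated criterion vocabulary, negated mentions,
    ambiguous abbreviations, ICD-9 codes with configurable error rates);
    builds bag-of-words and negation-aware concept feature matrices with
    Porter2 stemming and Gini-importance feature selection; fits an ICD-9
    rule baseline, naive Bayes, linear SVM, random forest and shallow
    neural network classifiers behind one train/predict contract; and
    implements classification by Bayesian inversion of per-class
    fine-tuned skip-gram embedding models with exact hierarchical-softmax
    sentence log-likelihoods. Includes a repeated stratified
    cross-validation harness with confidence intervals, external-test
    scoring, ROC export, and a label-permutation null test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    e1071,
    methods,
    nnet,
    ranger,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
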