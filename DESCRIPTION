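Package: genodrug
Title: Genetics-Informed Drug Activity Prediction with Multi-Label
    k-Nearest Neighbours
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Scores disease genes for druggability from multi-database
    provenance, derives genetics-based disease-indexed features for drugs,
    and predicts drug-disease activities with a weighted ensemble of
    multi-label k-nearest-neighbour (MLKNN) classifiers whose simplex
    weights are tuned by internal cross-validated area under the
    precision-recall curve.  Also provides the validation statistics used
    to audit such corpora: Tanimoto set similarity, Lin concept
    similarity, Czekanowski-Dice functional distance, a degree-preserving
    permutation test for drug-target associations, stratified
    clinically-active-ratio curves, and disease gene-profile rank
    correlation.  A synthetic corpus generator with a planted logistic
    indication model makes every stage testable without external
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
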