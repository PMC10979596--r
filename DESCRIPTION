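Package: kmpred
Title: Two-Stage Graph Neural Network and Gradient Boosting Prediction of
    Michaelis Constants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts log10 Michaelis constants (K_M) for wildtype and mutant
    enzyme-substrate pairs from substrate SMILES and protein sequence. Kinetic
    records are curated (mutation application, SMILES canonicalization,
    maximum-K_M deduplication, sequence-length filtering, log10 transform),
    substrates are converted to molecular graphs and encoded by one of four
    message-passing encoders (GIN, GCN, GAT or a combined GAT-GCN), proteins
    are embedded by a pluggable fixed-length embedder, and a two-stage model
    (graph encoder plus fully connected head trained end-to-end, followed by
    gradient-boosted trees on the combined 1,408-dimensional features) is fit
    to log10 K_M. Includes evaluation metrics with stratified reports by
    enzyme type and EC class, and a synthetic-data generator with a planted
    signal so the whole pipeline is testable without database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineOB,
    jsonlite,
    stats,
    utils,
    xgboost
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
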