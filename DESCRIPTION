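Package: heartledger
Title: Secured Heart-Disease Prediction with an Archimedes-Tuned Neural
    Classifier, Matrix-RSA Encryption and a Merkle Ledger
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, self-contained pipeline for secure clinical
    risk classification on Cleveland-schema heart-disease records.
    Synthetic patient cohorts with a known generative risk model are
    encrypted with a matrix-based (Hill-style) RSA block cipher,
    committed to a Merkle-rooted hash-chain ledger, audited for
    integrity, decrypted, and classified by a small neural network
    trained by explicit mini-batch SGD with momentum. Network
    hyperparameters (learning rate, momentum, epochs, dropout) are tuned
    by the Archimedes Optimization Algorithm using stratified
    cross-validated accuracy as the fitness. Includes the standard
    confusion-matrix evaluation metrics, Merkle inclusion proofs, tamper
    detection, a hash-chained audit log, and a reproducible run report.
    The cipher is educational and is not audited cryptography.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    openssl,
    stats,
    graphics,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
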