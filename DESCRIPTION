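Package: psbp
Title: Prediction of Polystyrene Surface-Binding Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for screening phage-display biopanning results for
    polystyrene surface-binding peptides (PSBPs), a common class of
    target-unrelated peptide. Provides peptide I/O and sequence hygiene,
    curation of balanced training sets with Generalized Jaccard similarity
    filtering, amino-acid and dipeptide composition encoding, F-score-ranked
    forward feature selection, RBF-kernel support vector machine training
    with probability estimates, stratified fivefold cross-validated
    evaluation (sensitivity, specificity, accuracy, Matthews correlation
    coefficient, ROC/AUC), and a synthetic peptide-dataset generator for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
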