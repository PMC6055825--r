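Package: dsqsar
Title: Docking-Score QSAR Models of Protein-Compound Binding Free Energy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts protein-compound binding free energies (kcal/mol) from a
    compound's docking scores against a panel of probe proteins. A compound is
    described by its docking-score vector; the score matrix is centred and
    decomposed by principal component analysis, predictive axes are selected by
    greedy forward search against leave-one-out cross-validated correlation, and
    coefficients are fitted by a Tikhonov-restrained least squares objective with
    an optional Tukey-type M-estimation (iteratively reweighted) robust variant.
    Includes conversion of heterogeneous assay records (Ki, IC50, percent
    inhibition or residual activity) to binding free energies, N-sigma replicate
    outlier elimination, leave-one-out and k-fold cross-validation with Q2/RMSE
    reporting, hyperparameter grid search, a synthetic low-rank data generator
    with planted outliers for validation, delimited-text readers and writers, and
    a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
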