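Package: vitabind
Title: Prediction of Protein-Vitamin Binding Residues from Sequence Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts vitamin-binding residues in protein sequences from
    sequence-derived profiles. Per-residue features combine a sliding window
    over a logistic-normalised position-specific scoring matrix (PSSM), a
    window over predicted secondary-structure probabilities, and a window over
    amino-acid vitamin-binding propensities estimated from labelled training
    residues. Several feature-subspace selectors (data variance, Fisher score,
    Laplacian score, and a joint Laplacian feature-weights learner with
    automatic subspace sizing) feed an ensemble of heterogeneous radial-basis
    C-SVMs whose calibrated scores are averaged and thresholded. Evaluation
    utilities implement sensitivity, specificity, accuracy, the Matthews
    correlation coefficient and ROC AUC, balanced and MCC-maximising threshold
    selection, and residue-level versus sequence-level k-fold cross-validation
    with pooled reporting. A synthetic data generator emits complete datasets
    in the same on-disk dialects (FASTA, PSI-BLAST ASCII PSSM, PSIPRED ss2,
    label files) with plantable binding signal for download-free benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
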