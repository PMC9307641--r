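Package: pathmil
Title: Weakly Supervised Multiple Instance Learning for Colon Histopathology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An annotation-free computational-pathology toolkit for colon
    histopathology. Extracts multilabel weak diagnoses (cancer, high- and
    low-grade dysplasia, hyperplastic polyp, normal) from free-text pathology
    reports with a rule-based concept recognizer and linker including negation
    detection, tiles slide rasters into 224x224 patch bags with
    saturation-based tissue masking, and trains an attention-pooling,
    instance-level multiple-instance-learning classifier on those bags using
    the report-derived labels. Ships the full evaluation protocol (multilabel
    micro-accuracy, support-weighted F1, Cohen's kappa, ROC/AUC, rank-sum
    comparisons, mislabeled-subset analysis, attention heatmaps, latent-space
    export), external label-scheme aggregation, and a paired synthetic
    report/slide generator with per-patch ground truth so every stage is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    nnet,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
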