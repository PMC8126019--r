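Package: habitomics
Title: Multiparametric MRI Radiomics for Glioblastoma Tumor Subregion
    Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Radiomics pipeline for classifying the four tissue habitats of
    glioblastoma (necrosis, solid part, peritumoral tissue, peritumoral edema)
    from co-registered multiparametric MRI (T1-CE, T2-WI, T2-FLAIR, ADC).
    Extracts a 1316-value feature vector per tumor subregion (first-order
    intensity statistics, local binary pattern histogram statistics, 3D shape
    descriptors, gray-level co-occurrence and run-length texture features, and
    aggregated SIFT descriptors), compares k-nearest-neighbour, naive Bayes,
    random forest and multilayer-perceptron classifiers under leave-one-out
    cross-validation with one-vs-rest metrics and ROC/AUC, and ranks features
    by random-forest importance with Pearson/Spearman correlation analysis.
    Includes a synthetic multiparametric phantom generator so the whole
    pipeline is testable without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    ranger,
    e1071,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    pheatmap,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
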