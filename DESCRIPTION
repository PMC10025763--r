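Package: transXplain
Title: Assessment and Optimization of Attribution Explainers for
    Transcriptomic Tissue Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Trains multilayer-perceptron and convolutional tissue
    classifiers on log2(TPM+1) expression matrices and interprets them with
    eight backpropagation-based attribution explainers (Saliency, Input x
    Gradient, guided backpropagation, Integrated Gradients, DeepLIFT rescale
    rule, DeepLIFT-based SHAP approximation, Guided Grad-CAM and Guided
    Grad-CAM++), all implemented from first principles with exact
    reverse-mode gradients. Provides the four baseline-reference families
    (zero, normal, universal, specific) used by difference-from-reference
    explainers, four optimization protocols that quantify attribution
    reproducibility (noise-averaged pseudo-samples, simple repeats under
    enabled dropout, reference-count averaging, and model aggregation) via
    pairwise Spearman correlation and top-k gene overlap, and a
    biological-relevance stage that classifies housekeeping and
    tissue-enhanced genes, tests Mann-Whitney differential expression with
    FDR and fold-change filters, and scores marker-gene recovery. A
    synthetic-cohort generator with planted tissue markers, housekeeping
    genes and normal/cancer fold changes supplies ground truth for
    benchmarking.
License: MIT
Encoding: UTF-8
Depends:
    R (>= 4.3),
    SummarizedExperiment
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
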