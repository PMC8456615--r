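Package: tumorvae
Title: Semi-Supervised Variational Autoencoder Features for Chemotherapy
    Response Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts tumor response to chemotherapy from bulk transcriptome
    profiles with a semi-supervised pipeline: median-absolute-deviation
    variance filtering of genes, min-max scaled log2 total-count-normalized
    expression, a variational autoencoder (VAE) trained on all tumors
    (labeled and unlabeled) with configurable L1/L2/cross-entropy
    reconstruction loss, and gradient-boosted decision trees fitted on the
    latent encodings of the clinically labeled subset. Includes plain
    autoencoder, PCA and ICA baseline encoders, clinical response-label
    parsing for Xena- and cBioPortal-style annotation tables, a replicated
    stratified cross-validation harness with pooled AUROC/AUPRC and
    logit-scale Welch comparisons, two-dimensional embedding diagnostics,
    and a synthetic cohort generator for end-to-end testing without any
    external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    xgboost,
    e1071
Suggests:
    testthat (>= 3.0.0),
    pROC,
    mclust,
    optparse
Config/testthat/edition: 3
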