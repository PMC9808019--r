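Package: wsimil
Title: Weakly Supervised Multiple-Instance Learning for Whole-Slide Image
    Classification of Coeliac Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end multiple-instance-learning (MIL) pipeline for
    classifying H&E-stained duodenal-biopsy whole-slide images as normal or
    coeliac disease from slide-level labels only. Provides deterministic
    sliding-window tile extraction with Otsu-based background rejection,
    Macenko stain normalisation in optical-density space, weakly supervised
    bag training with top-k proxy labelling and gradient masking over a
    pluggable two-head patch classifier (a compact CNN backbone is included),
    mean-score slide classification with independently thresholded class
    heads, case-grouped stratified cross-validation with ROC/PR analysis and
    balance-point threshold selection, patch-prediction localisation
    heatmaps, and a seeded synthetic H&E slide generator with ground-truth
    lesion masks for download-free testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    png,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
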