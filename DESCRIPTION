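Package: slideuq
Title: Uncertainty-Aware Patch-Based Classification of Whole-Slide Images
Version: 0.1.0
Authors@R:
    person("slideuq", "developers", email = "slideuq@example.org",
           role = c("aut", "cre"))
Description: A desk-scale framework for weakly supervised, patch-based
    diagnosis of pyramidal whole-slide images with Monte-Carlo-dropout
    uncertainty. Provides a seeded synthetic slide generator (two visually
    similar texture classes, stain-shifted external-centre variants and
    out-of-distribution textures), multi-resolution pyramid construction
    and 299x299 grid tiling with tissue filtering, a small convolutional
    classifier with dropout kept active at inference, slide-level diagnosis
    by averaging patch predictions, and uncertainty evaluation tools:
    ROC/AUC, global and class-specific uncertainty-rejection curves,
    variance-threshold out-of-distribution reports and kernel density
    summaries of uncertainty distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
VignetteBuilder: knitr
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
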