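Package: endoscreen
Title: Two-Stage Quality Filtering and Referral Triage for Endoscopic Video
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A screening toolkit for flexible nasopharyngoscopy video built
    around two cooperating stages: an image quality module that discards
    redundant, blurred, obscured or off-target frames (histogram-of-gradients
    similarity filtering, U-Net derived weak quality labels, and an efficient
    convolutional quality classifier), and a disease classification module
    that averages frame-level referral probabilities into a patient-level
    referral decision. Includes a synthetic endoscopy cohort generator with
    ground-truth glottis masks, a compact CPU convolutional network engine
    (Ghost modules, residual and inverted-residual blocks, U-Net), analytic
    FLOP accounting for the supported architectures, evaluation metrics with
    leak-free patient-level splitting, and an ablation harness for the frame
    budget.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jpeg,
    jsonlite,
    png,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
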