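Package: cescore
Title: Automated Small-Bowel Cleansing Quality Scoring for Capsule Endoscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated assessment of small-bowel preparation quality from
    capsule endoscopy frame sequences. Converts frames to the gray, HSV
    saturation and CIELAB b* channels, assigns each frame a 5-point
    cleansing score (rule-based visible-mucosa estimation or a small
    trainable convolutional classifier with softmax score assignment),
    aggregates per-frame scores into a case-level average cleansing score,
    derives segmental and overall A/B/C preparation grades with an adequacy
    call on a validated quantitative scale, and provides the matching
    evaluation statistics (Top-1 accuracy, Cohen's kappa, group comparison,
    ROC analysis with Youden cut-off selection). Includes a synthetic frame
    generator with known ground-truth mucosal visibility so the whole
    pipeline can be exercised end to end without clinical data.
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
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    e1071,
    farver,
    jpeg,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
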