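Package: tilebayes
Title: Bayesian Uncertainty-Aware Classification of Histopathology Tiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classification of small histopathology tissue tiles with a
    dropout-regularised dual-head convolutional network whose Monte-Carlo
    (variational dropout) predictive posterior yields two uncertainty
    measures, predictive entropy H and BALD mutual information. The
    uncertainty drives a pool-based active-learning acquisition loop, a
    detector of mislabelled training tiles (confident misclassifications
    below a per-class entropy percentile), and tile-based whole-slide
    segmentation with class surface-area statistics. Includes a procedural
    generator of textured tiles and composite slides with known region
    masks for benchmarking, plus one-vs-all ROC and precision-recall
    evaluation under repeated stratified holdouts.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
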