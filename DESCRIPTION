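Package: podyield
Title: Soybean Yield Prediction from Pod and Leaf Counts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Tools for in-situ soybean yield prediction from organ counts
    extracted from potted-plant images. Provides bounding-box geometry with
    IoU and Distance-IoU (DIoU) similarity and loss, k-means++ clustering of
    labelled box dimensions into detector anchor priors, edge-preserving
    guided-filter denoising and gamma enhancement with box-aware data
    augmentation, greedy matching of predicted to ground-truth boxes with
    precision/recall/F1/mAP evaluation, a generalized regression neural
    network (Nadaraya-Watson kernel regression) that maps leaf and pod-type
    counts to per-pot seed number (with partial least squares and
    back-propagation baselines), and conversion of pod-type counts to grain
    mass via per-pod-type seed weights. A seeded synthetic-scene generator
    emulates pots of four plants photographed from four directions with
    leaves occluding colour-similar pods, so the full pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    nnet,
    png,
    withr,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
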