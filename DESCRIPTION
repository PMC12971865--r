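Package: gazeskill
Title: AOI-Dependent Gaze and Tool-Motion Analytics for Laparoscopic Skill Assessment
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Extracts area-of-interest (AOI) dependent eye-tracking metrics and a
    tool-motion metric from per-frame instance annotations (COCO-style polygons for
    pegboard objects and laparoscopic graspers) combined with a raw gaze trace, for
    the FLS peg-transfer training task. Fixations are identified with a
    velocity-threshold (I-VT) filter; fixations are scored against dilated instance
    contours to yield five fixation-rate metrics plus grasper speed. Sessions are
    clustered (k-means++ with elbow selection on the within-cluster sum of squares)
    into visual-behavior levels, merged into skill levels by completion-time post
    hocs (Welch ANOVA, Games-Howell), compared per metric (one-way ANOVA with Tukey
    HSD), and predicted with four classifier families (random forest, RBF support
    vector machine, CART, single-hidden-layer neural network) under leave-one-out
    cross-validation with Gini feature importance. A synthetic peg-transfer session
    simulator with skill archetypes makes the full pipeline testable without real
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    jsonlite,
    quadprog,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
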