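Package: mgsflow
Title: Automated Mouse Grimace Scoring and Pose-Based Behavior-Flow Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A cascaded video-analysis workflow for cage-side welfare monitoring
    of laboratory mice: frame-quality scoring and best-frame selection from
    front-camera video, face detection and crop preprocessing, multi-head
    mouse-grimace-scale (MGS) classification with leave-one-animal-out
    cross-validation and a desk-scale training harness, session-level CSV
    outputs, and a pose-based behavior-flow stage (keypoint feature
    engineering, k-means behavioral clustering, transition-matrix group
    comparison, arena-calibrated distance moved). Ships a fully parametric
    synthetic-data generator (procedural grimace faces with quality ground
    truth, regime-switching keypoint trajectories, multi-group cohorts) so
    every stage is trainable and testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    nnet
Config/testthat/edition: 3
biocViews: Classification, Clustering, Visualization
RoxygenNote: 7.3.3
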