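Package: orssg
Title: Semantic Scene Graphs for Operating Room Activity Modeling
Version: 0.1.0
Authors@R:
    person("ORSSG", "Developers", email = "orssg@example.org", role = c("aut", "cre"))
Description: Tools for holistic modeling of operating room (OR) activity with
    3D semantic scene graphs. Provides typed scene-graph containers with JSON
    serialization, a procedural simulator of total knee replacement takes
    (colored point clouds, multi-view images, 14-joint skeletons, object
    boxes, ground-truth graphs, clinical roles and surgical phases), geometric
    instance labeling of fused point clouds, point-cloud augmentation,
    a multimodal PointNet-style scene-graph generation network with graph
    convolutional contextualization and class-balanced training, Hungarian
    skeleton tracking with greedy bijective clinical-role assignment (plus a
    learned graph-encoder scorer), a transparent rule engine recognizing the
    eight phases of a knee replacement workflow, and macro-averaged
    precision/recall/F1 evaluation for relations, roles and phases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
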