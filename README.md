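# orssg — semantic scene graphs for operating-room activity modeling

Surgical data science increasingly asks not just *what phase* a surgery is
in, but *who is doing what to whom with what* in the operating room (OR).
`orssg` is an R toolkit for that question, built around **3D semantic scene
graphs (SSGs)**: per-second snapshots of a total knee replacement OR in
which nodes are entities (staff, patient, operating table, anesthesia
equipment, instruments) and directed, typed edges are semantic relations
(`head surgeon --Sawing--> patient`, `patient --LyingOn--> operating
table`).

Formally a scene graph is `G = (N, E)` with `E ⊆ N × R × N`, where `R` is a
closed 14-relation vocabulary plus a reserved background class `None` that
classifiers score but graphs never store. On top of this representation the
package provides the full pipeline of the 4D-OR knee-replacement modeling
approach:

* **`ssg_core`** — typed graph/sequence containers, validation, triplet
  queries, JSON serialization.
* **`synthetic_or`** — a procedural simulator of 1 Hz, ~11 minute takes:
  colored point clouds, multi-view orthographic images, 14-joint skeletons,
  object boxes, ground-truth graphs, clinical roles and the eight-phase
  schedule. Instruments share a single shape and differ **only in color**,
  so tool-use relations are deliberately unreadable from human–patient pair
  geometry and readable from images — a controlled testbed for the
  multimodal claim.
* **`instance_labels`** — geometric point labeling from detected poses and
  boxes (boxes > bodies > hand-held instruments > background), plus
  fixed-size entity/pair samplers (4000 / 8000 points at benchmark scale).
* **`augment`** — the three training-time augmentation families: global
  scale/position/orientation/brightness/hue, independent per-entity moves
  inside relation pairs, and crop-to-hand.
* **`sgg_net`** — the multimodal scene-graph generation network:
  PointNet-style object and pair encoders (shared per-point MLP + max
  pooling), a pluggable global image encoder fused by concatenation,
  edge-conditioned graph-convolution rounds, and class-balanced
  cross-entropy training (`w_c ∝ 1 − n_c/Σn`). Implemented natively in R
  with hand-verified reverse-mode gradients; no deep-learning framework
  required.
* **`tracking_roles`** — Hungarian matching of skeletons into tracks, role
  likelihoods per track (transparent relation-frequency heuristic, or a
  learned target-marked graph encoder), and the printed **greedy bijective
  role assignment**: repeatedly take the globally most probable
  (track, role) pair, delete the role, renormalize.
* **`phase_rules`** — the annotation-free eight-phase rule engine driven by
  triplet queries on role-augmented graphs with latched
  surgery-started/finished flags.
* **`eval_metrics`** — per-class and macro precision/recall/F1 for
  relations (over ordered ground-truth entity pairs, `None` included),
  roles and phases.

## Worked example

```r
library(orssg)

# simulate a 2-minute take and recover phases from the ground-truth graphs
b  <- simulate_timeline(sim_config(seed = 3, take_length_s = 120),
                        geometry = FALSE)
sq <- take_sequence(b, with_roles = TRUE)
mean(recognize_phases(sq) == vapply(b, `[[`, "", "gt_phase"))
#> [1] 1

# assign clinical roles from tracks + heuristic scores + greedy matching
res <- assign_take_roles(lapply(b, `[[`, "poses"), take_sequence(b))
res$node_roles[c("hs", "as", "cn", "an", "patient")]
#>                  hs                  as                  cn
#>      "head surgeon" "assistant surgeon" "circulating nurse"
#>                  an             patient
#>       "anaesthetist"           "patient"

# benchmark worked example: macro averages from the published per-class table
rel <- fourdor_reference_scores("relations")
round(c(macro_average(rel$precision), macro_average(rel$recall),
        macro_average(rel$f1)), 2)
#> [1] 0.80 0.86 0.81
harmonic_f1(0.36, 0.72)   # the Cutting column
#> [1] 0.48
```

The first block shows the pipeline's self-consistency: on noiseless
simulated takes the rule engine reproduces the simulator's phase labels on
100% of frames, and the greedy assigner recovers all five clinical roles.
The last block recomputes the published benchmark's macro rows from its
printed per-class values with this package's metric functions.

Training the scene-graph network end-to-end on 200 simulated frames
(`tests/testthat/test-acceptance.R`, criterion 5) reaches held-out relation
macro-F1 ≈ 0.92 in a few minutes on one CPU — the desk-scale analogue of
the benchmark's 0.81 — and the image-fusion ablation there shows the
mechanism: without images, color-coded tool-use relations collapse.

## CLI

`exec/orssg` (or `Rscript -e 'orssg::orssg_cli()' ...`) exposes
`validate`, `simulate`, `phases`, `eval` and `roles` subcommands over the
JSON/PLY/PPM on-disk formats.
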