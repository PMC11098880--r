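---
title: "Modeling the operating room with semantic scene graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the operating room with semantic scene graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(orssg)
```

## The model

A semantic scene graph `G = (N, E)` describes one time point of an
operating room: nodes `N` are typed entities (medical staff, the patient,
equipment), and `E ⊆ N × R × N` is a set of directed edges labeled with one
of 14 semantic relations (Assisting, Cementing, Cleaning, CloseTo, Cutting,
Drilling, Hammering, Holding, LyingOn, Operating, Preparing, Sawing,
Suturing, Touching). A fifteenth label, `None`, exists only for
classifiers and evaluation: relation heads score it for every ordered
entity pair, but a graph never stores a `None` edge. Since the relation
head is a softmax over labels, a graph carries **at most one relation per
ordered pair**; a symmetric predicate such as CloseTo simply appears once
per direction.

A take is a 1 Hz sequence of such graphs over a whole simulated total knee
replacement (~11 minutes). Downstream reasoning uses only the graphs: role
assignment reads relation statistics per person, and phase recognition
queries class-level triplets such as *head surgeon hammering patient*.

## What the simulator states, and what it does not

The built-in simulator (`sim_config()`, `simulate_timeline()`) is the
package's stated world; every training and acceptance experiment runs on
it. Its fixed facts:

* 1 frame per second; default take length 660 s; six orthographic ceiling
  views; 14-joint skeletons (head, neck, and left/right shoulder, elbow,
  wrist, hip, knee, ankle).
* Five clinical roles (patient, head surgeon, assistant surgeon,
  circulating nurse, anaesthetist) constant within a take; four staff
  stations around a fixed equipment layout.
* The eight canonical phases in order, with durations proportional to
  `phase_duration_weights` (defaults chosen as plausible fractions of a
  knee replacement; real duration distributions are not published, so the
  weights are free parameters).
* Within each phase, scripted phase-defining actions: joint
  patient-preparation by both surgeons; cutting/drilling/sawing in the
  first operative phase; hammering (with interleaved operating and
  suturing) during implant placement; cementing throughout the conclusion.
  The script guarantees geometric consistency — the acting wrist is within
  0.4 m of the patient's knee and the scripted instrument's points sit at
  the hand — and the first frame of each operative phase fires that
  phase's defining rule, which is what makes 100% phase self-consistency a
  *constructional* property rather than an empirical accident.
* Geometric relations are predicates: CloseTo iff centroid distance
  < 1.5 m (emitted with a human subject, both directions for human–human
  pairs), LyingOn iff a torso centroid is horizontally inside a table
  footprint and 0–0.5 m above its top. Scripted action edges take
  precedence over LyingOn, which takes precedence over CloseTo, so the
  one-relation-per-pair invariant holds.
* **Color-only instrument coding**: all instruments are the same small
  block; only the color (eight saturated colors on an otherwise muted
  palette) identifies the tool and hence the action. Consequently the
  union cloud of a (surgeon, patient) pair carries *no* information about
  which tool is in use — the instrument is a separate entity — and the
  global image feature is the only path to distinguishing Cutting,
  Drilling, Sawing, Hammering, Suturing and Cementing. This is the
  controlled mechanism behind the images-help ablation.

What the simulator does **not** emulate: photorealism, occlusion and cloth,
sensor-specific depth noise (only Gaussian jitter), crowd variability,
camera calibration error, and any ambiguity about who performs an action.
A green test on simulated takes therefore establishes that the pipeline's
machinery is correct and that its inductive mechanisms (multimodality,
class balancing, smoothing) behave as designed — not that the network
would reach the same scores on real RGB-D captures.

## Instance labeling

`compute_instance_labels()` assigns each point by precedence: inside a
detected box → that object (overlaps resolve to the nearest box center,
and boxes are inflated by `box_margin = 0.02` m to absorb jitter at
faces); within `r_body = 0.15` m of a skeleton bone → nearest person;
within `r_hand = 0.25` m of a wrist → that person's virtual instrument,
provided at least 20 points qualify (fewer points are left as background
and the instrument node, being virtual, simply has no geometry); else
background. The radii are unpublished upstream; 0.15 m approximates limb
thickness and 0.25 m a held tool, and both are configurable. On simulator
frames with ground-truth poses and boxes, ≥ 95% of non-background points
recover their generating entity; the residual is genuine boundary
ambiguity (points where a hand hovers over a table edge, patient points
grazing the table plane).

## The network and its numerical choices

Both point encoders are shared two-layer per-point MLPs followed by
column-wise max pooling per entity (or per pair, with a subject/object
indicator channel), which makes them exactly permutation- and
duplication-invariant. Per-point inputs are local coordinates (centered
per cloud), RGB, and the cloud centroid as constant channels, so both
shape and absolute position are visible. Empty entities (a virtual
instrument with no points) use a learned missing-geometry embedding.

The default image encoder is a 1×1-convolutional net over the foreground
pixels of all views — a shared per-pixel MLP on (r, g, b, x, y) with
global max pooling — trained end-to-end. Max pooling is essential: a
several-pixel instrument blob survives it, where average pooling would
wash it out. Above the pixel budget, saturated pixels are always kept and
the grey mass is stride-subsampled (deterministically), for the same
reason. The encoder is pluggable; any callable producing a fixed-length
global vector can replace it, and heavyweight pretrained backbones are
deliberately out of scope. Fusion is concatenation of the global image
vector to every node and edge feature.

Contextualization is `gcn_layers = 2` rounds of edge-conditioned message
passing on the fully connected candidate graph: each edge updates from
(subject, edge, object), each node from (itself, mean over transformed
(neighbor, outgoing-edge) pairs). Heads are linear. Training minimizes
weighted cross-entropy over node classes plus pair relations, with every
unordered-pair ordering lacking a ground-truth edge supervised as `None`
(no negative subsampling at this scale). Class balancing is the linear
rule `w_c ∝ 1 − n_c/Σn`, renormalized to mean 1; `mode = "none"` recovers
plain cross-entropy exactly.

All gradients are hand-written reverse-mode and are verified against
central finite differences in the test suite (the only disagreements occur
exactly at ReLU kinks, where the subgradient 0 is used). The optimizer is
Adam with one step per frame. The benchmark-scale defaults (4000/8000
points, learning rate 3e-5, feature width 128) are kept as configuration
defaults; the desk-scale acceptance experiments use 128-point budgets,
width 48 and learning rate 2e-3, a deliberate scaling-down to a single
CPU — thresholds are unchanged, and the scaled runs exceed them with
margin (held-out macro-F1 ≈ 0.92 against the 0.80 gate).

## Tracking, roles, phases

Tracking links detections frame-to-frame by minimum mean 14-joint distance
using an exact O(n³) Hungarian solver (validated against brute-force
enumeration); links costlier than the 0.8 m gate terminate a track. A
track keeps `K = min(length, 32)` graphs sampled uniformly along its
extent — the selection rule is unspecified upstream, and uniform sampling
bounds cost while covering the take.

The heuristic role scorer counts role-typical relations around the
track's node (tool-use as subject → head surgeon; LyingOn as subject and
tool-use as object → patient; Assisting/Holding/Preparing → assistant;
contact or proximity with the instrument table → circulating nurse; with
the anesthesia equipment → anaesthetist), Laplace-smooths and normalizes.
Note that an individual row can be wrong-headed in isolation — the head
surgeon also holds instruments and prepares the patient — and the greedy
*bijective* assignment is what resolves such overlaps: the assistant's
purer profile claims "assistant surgeon" first, and the head surgeon's
role follows by elimination. The assignment is the printed sequential
procedure (global max, delete role, renormalize, repeat; ties break by
track index then role order), not a globally optimal matching; a
Hungarian variant is available behind `method = "hungarian"` for
comparison. The learned scorer is a compact target-flagged message-passing
graph encoder standing in, contract-equivalently, for a graph transformer.

The phase engine evaluates the eight rules in priority order — specific
operative triplets (cementing, hammering, cutting, joint preparing) before
presence rules — which is the only reading under which the rule list is
mutually consistent. The two latched flags operationalize "surgery
started" (first operative or joint-preparation triplet) and "surgery
finished" (first frame after cementing has been seen on which no operative
triplet fires; cementing marks the conclusion, so cessation of operative
actions afterwards ends the surgery). Roll-in and roll-out are otherwise
identical patient-presence rules disambiguated purely by the flags.
Optional odd-window majority smoothing absorbs noise in predicted graphs;
it is **disabled by default** (`w = 1`) to keep the engine exactly the
rule list, and the smoothing-benefit experiment enables `w = 5`.

## Evaluation protocol

Relations are scored over the ordered pairs of entities present in the
ground-truth scene: the predicted label for a pair (or `None` when no edge
is predicted) meets the ground-truth label in a 15-class confusion matrix;
predicted edges touching hallucinated entities are ignored, since entity
detection is scored upstream. Macro averages are unweighted means over all
15 classes *including* `None` — the published macro rows are arithmetically
consistent with inclusion, which settles that choice — and a flag excludes
it. One refinement: a class absent from both truth and prediction is
listed with zero scores but excluded from the macro, so that a perfect
prediction on a scene covering only some classes scores 1.0 rather than
being penalized for classes that never occur; on any evaluation where all
classes appear (the benchmark tables, the acceptance experiments) this
changes nothing. Roles (5 classes) and phases (8 classes) reuse the same machinery.
Reports print at two decimals; full precision is kept internally.

## Known limitations

* The simulator's separability means desk-scale scores overstate what any
  real capture would yield; only directions and mechanisms transfer.
* The heuristic evidence table is a configurable superset of the two
  published examples; its exact upstream form is unknown.
* Tracking has no re-identification: any full occlusion (or an empty
  frame) births a new track.
* The phase engine's finished-flag semantics are one defensible
  operationalization of prose that does not define them; both the trigger
  and the rule priority are documented above and configurable in code.
* PLY and PPM (not PNG) are the on-disk image/cloud formats: both are
  plain text, which the deliverable requires and base R can read without
  extra dependencies.
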