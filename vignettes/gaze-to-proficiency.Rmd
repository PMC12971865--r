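---
title: "From gaze and instance masks to skill levels: the methods behind gazeskill"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From gaze and instance masks to skill levels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazeskill)
```

## The problem

In FLS peg-transfer training, a trainee lifts six rubber triangles with a
grasper held in the non-dominant hand, transfers each mid-air to the dominant
hand, and places it on the opposite side of the pegboard. Where the trainee
*looks* while doing this carries skill information: skilled performers direct
their gaze at the objects being manipulated, while unskilled performers follow
their instruments ("tool-following" gaze) and move them faster and more
erratically. Scoring gaze against such scene content is hard because the areas
of interest (AOIs) — objects and graspers — move every frame. gazeskill
consumes per-frame *instance masks* (COCO-style polygons with detection
scores, the output contract of an instance-segmentation model) together with
the raw gaze trace and turns them into per-session behavioural metrics, then
into skill levels and predictions.

## Pipeline and models

### I-VT fixation filtering

Raw gaze at a nominal 50 Hz is segmented with a velocity-threshold (I-VT)
filter: samples whose angular velocity is below **70 deg/s** belong to
fixations. Velocity is a two-point estimate across a symmetric
`velocity_window` (default 20 ms): for each sample we take the nearest valid
samples at or beyond half a window on either side and divide their angular
separation by their time separation. This attenuates sensor noise relative to
adjacent-sample differencing. Runs below threshold become fixations; invalid
gaps up to `max_gap_fill` (75 ms) inside a run are bridged; runs shorter than
`min_fixation_duration` (60 ms) are discarded; the fixation centroid is the
mean position of its member samples. Only the 70 deg/s threshold is a
published constant — window, minimum duration and gap fill follow common I-VT
practice and are configurable.

Degrees require a geometry. Eye trackers resolve this internally, but an
offline reimplementation must be explicit: `screen_geometry()` defaults to
38 px/degree (a typical seated-monitor value) or derives the factor from
viewing distance and screen dimensions. Absolute threshold behaviour depends
on this choice; all relative comparisons in the package do not.

### Dilated-contour hit testing and AOI categories

For every video frame whose timestamp falls inside a fixation's
`[t_start, t_end]`, the fixation centroid is tested against each detected
instance: a hit is a point inside the polygon or within `dilation_radius`
(default **5 px**) of its contour, which absorbs fixations just outside a
mask boundary. Detections with confidence not exceeding **0.5** are dropped
at load time.

A hit is assigned one of five categories. An object's *holding state* is the
number of grasper polygons overlapping it (intersection area above a small
tolerance, clamped at two). A fixation-frame pair that hits an object is
categorised by the most-held hit object — `OBJ_1TOOL`, `OBJ_2TOOLS`, or
`OBJ_NOT_MOVING` for an unheld object (the feedforward "next target"
category); object hits take precedence over tools; a tool-only hit is
`TOOL_ONLY`; otherwise `NONE`. The category names describe object *state*
("moving object manipulated by one tool"), which is the default semantics; a
literal mode (`category_semantics = "pixel_intersection"`) instead asks
whether the point itself lies in the object-grasper overlap region, for users
who read the category definitions that way. Under the default semantics the
three object subcategories partition the object hits exactly, which the test
suite asserts to 1e-12.

Frames are credited at most once per category however many fixations cover
them, so rates are bounded by the frame rate. Whether the original analysis
deduplicated this way is not documented; we chose the bounded reading.

### The six metrics

Five fixation rates (frames/second): distinct frames credited to tools,
objects (union of the three subcategories), object-one-tool, object-two-tools
and not-moving objects, each divided by task completion time. One motion
metric: **tool speed** (px/s), the average over consecutive detected-frame
pairs of grasper-centroid displacement over the timestamp difference, summed
over the left and right graspers. Grasper identity is assigned by centroid
x-order with nearest-centroid continuity when the instruments cross; pairs
spanning a missed detection are skipped rather than interpolated, so
occlusion does not fabricate motion. Frame-wise agreement between two
annotation sources is quantified with Cohen's kappa (defined as 1 when both
sequences are the same constant).

### Skill-level discovery (clustering)

Sessions are clustered on the six metrics only — completion time and errors
are reserved for *interpreting* the clusters. Features are z-standardized
(tool speed is hundreds of px/s and would otherwise dominate Euclidean
distance), then k-means++ with Lloyd iterations, best of `n_init` restarts,
is run for k = 1..8 and k is chosen at the maximum second difference
(discrete curvature) of the WCSS curve, ties to the smaller k; a numerically
straight curve is flagged `no_clear_elbow`.

Clusters are interpreted by completion time: Levene's (Brown-Forsythe) test
decides between the classic one-way ANOVA and Welch's ANOVA; Games-Howell
post hocs compare all cluster pairs; clusters whose pairwise comparison is
non-significant at alpha = 0.05 are merged (connected components of the
non-significance graph), and the resulting levels are ordered fastest-first.
When three clusters merge into two levels they are labelled `HIGH` and
`MID_LOW`, the canonical outcome for early-stage novices. Per-metric
differences between clusters use one-way ANOVA with Tukey HSD (or Welch plus
Games-Howell when variances are heterogeneous). Trainer-anatomy effects use a
paired t-test on participants who performed on both box trainers and a Welch
independent t-test on the rest.

### Visual-behaviour prediction

Four classifier families predict the cluster-derived levels from the six
metrics under leave-one-out cross-validation: random forest (500 Gini trees,
`mtry = floor(sqrt(d))`), an RBF-kernel soft-margin SVM (`C = 1`,
`gamma = 1/d`, one-vs-one, solved as a dual QP), CART (a single Gini tree),
and a one-hidden-layer (8 unit, tanh) softmax network trained with BFGS and
weight decay 1e-3. The hyperparameters are package choices — the methodology
this package implements names the families but not their settings. All fold
statistics, including the z-scaling used by SVM and ANN, are fitted on the
n − 1 training rows only; folds whose training part lacks a class are
excluded with a warning. F1 is the binary F1 for two classes and macro-F1
otherwise, recorded in the report. Random-forest Gini importance is the
normalized mean decrease in node impurity.

None of the usual machine-learning packages are assumed at run time: the
Gini tree is implemented in C++ (shared by CART and the forest), the SVM dual
is solved with `quadprog`, and the network is fitted with `stats::optim`.

## The synthetic session generator

No recordings are deposited with the study this package operationalizes, so
`simulate_session()` / `simulate_cohort()` generate complete sessions —
COCO-style polygon annotations at 25 fps on a 1920x1080 arena, a 50 Hz gaze
trace, and session metadata — conditioned on three skill archetypes
(HIGH/MID/LOW). The default cohort is 24 sessions shaped 5/14/5 from 18
participants, six of whom perform on both an adult and a pediatric box
trainer.

What the generator emulates, and the stated-world defaults:

* **Task script.** Six triangles transferred sequentially: reach, a hover at
  a standoff point, grasp, carry, a two-grasper mid-air transfer, place.
  Sub-phase durations scale with the per-object segment (90% active, 10%
  hover), so each gaze target exists for the same share of every session and
  the gaze policy alone controls AOI allocation; pace differences appear as
  scripted grasper speed.
* **Completion times.** Normal with archetype means 120/233/282 s (sds
  20/45/50), echoing the published cluster differences in sign: the HIGH
  archetype is clearly faster, MID and LOW overlap enough that their
  Games-Howell comparison is typically non-significant — the configuration
  the level-merging logic is designed for.
* **Gaze policy.** Each dwell (gamma-distributed, mean 0.35 s) aims at the
  held object, the next object, the active grasper, or the background, with
  archetype probabilities. The defaults reproduce the published
  directionality *and* its structure: object-directed rates separate HIGH
  from both other archetypes, while tool rate, not-moving rate and tool
  speed separate LOW; MID shares the former group of metrics with LOW and
  the latter with HIGH. This mirrors the published pairwise tables (where
  the middle cluster was indistinguishable from the slow cluster on object
  metrics and from the fast cluster on tool metrics) and, geometrically,
  places the three archetype centres at a right angle in z-space rather than
  on a line — which is also what makes the WCSS elbow unambiguous. A purely
  "midway MID" parameterization was tried first and makes the elbow rule
  prefer k = 2; it was replaced at design time.
* **Not-moving-object gaze.** The LOW archetype looks *more* at static
  objects (next-object weight 0.17 vs 0.07), matching the published finding
  that low-skill novices' drops pulled gaze to stationary objects and
  refuting the feedforward hypothesis. Drop events additionally teleport an
  object to a free location and pin gaze to it for 1.5 s; drops are Poisson
  with archetype means 0.5/1.5/2.5.
* **Kinematics.** Grasper tips follow piecewise-linear keyframe paths plus a
  small-amplitude AR(1) wander whose per-frame step is rescaled to the
  archetype's `speed_scale` (250/300/390 px/s per grasper); measured tool
  speed is this wander plus scripted motion, so LOW's instruments are
  measurably faster and more erratic.
* **Gaze realism.** Isotropic 8 px jitter per sample, 97% validity, a ~180 px
  corrective overshoot at every dwell boundary (without it, consecutive
  same-target pursuit dwells merge into long fixations whose centroid lags a
  moving object and the hit test loses them), and 0.5% per-instance detection
  dropout.

What it does **not** emulate: photorealistic appearance, grasp physics,
segmentation-mask shape errors (masks are exact triangles/quadrilaterals with
only a confidence score and dropout), learning across trials, or head
movement. A green test on synthetic data therefore establishes that the
*pipeline* measures what it claims on data whose ground truth is known — not
that any particular clinical cohort will separate.

## Numerical choices and degenerate inputs

* Polygon primitives are exact (shoelace area/centroid, Sutherland-Hodgman
  clipping against the convex grasper quadrilateral, signed point-boundary
  distance); the rasterized distance-transform oracle in the tests allows a
  ±0.5 px band around the dilated contour for grid effects.
* Object-state overlap tolerance is 0.5 px² — contact of mask boundaries is
  not "holding".
* Fewer than two valid gaze samples yield a flagged empty velocity series;
  an empty trace yields zero fixations and zero rates; a session with no
  grasper detected in two adjacent frames has undefined (NA) tool speed with
  a warning.
* Welch's ANOVA with all-zero group variances is flagged NA; Games-Howell
  with a zero standard error degenerates to p ∈ {0, 1} by mean equality.
* k-means ties and seeding use R's RNG under the caller's seed; duplicate
  rows always co-cluster; constant features are dropped with a warning
  before standardization.
* The elbow needs k_max ≥ 3; a straight WCSS line selects k = 2 and is
  flagged.

## Design choices on genuinely open points

* **Category semantics.** "Fixation on an object held by one tool" is read as
  object-state, not literal pixel intersection (default, with the literal
  mode retained); this makes the subcategory partition exact and matches the
  category names.
* **Prediction labels.** The default target is the three cluster labels; a
  two-level (HIGH vs MID_LOW) mode falls out of `assign_skill_levels()` when
  the user prefers the merged labels.
* **Importance stability.** For the feature-importance *experiment* shipped
  in the acceptance suite, importance is computed from bagged Gini trees
  (`mtry = d`): with `mtry = sqrt(d)` the impurity credit for one class
  boundary is split at random among the strongly correlated object
  subcategory rates, making rankings unstable even when a single CART
  concentrates all importance on the two truly informative features. The
  *prediction* default remains `mtry = floor(sqrt(d))`.
* **Per-grasper speed pairing.** Tool speed averages each grasper's
  consecutive detected pairs independently (no requirement that both tools be
  visible), then sums.

## Known limitations

* Sessions within an archetype share one gaze policy; real trainees vary, so
  synthetic clusters are tighter than clinical ones.
* The px-per-degree default is a convention; absolute I-VT behaviour (not the
  relative comparisons) depends on it.
* The generator's completion-time/idle coupling means extremely short
  sessions (duration_scale well below ~0.3) speed up scripted motion and
  degrade hit efficiency; runtime-scaled tests use it only where hit
  efficiency is not load-bearing.
* Mask quality is emulated only through the confidence score and dropout;
  polygon distortion of real segmentation models is out of scope.
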