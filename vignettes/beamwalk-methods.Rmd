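---
title: "Methods: automated beam-walk phenotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated beam-walk phenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beamwalkr)
```

## The assay and its data

In the beam-walk assay a mouse traverses a 1-m elevated beam toward a goal
box while a side-view camera records it at a nominal 120 fps. Marker-less
pose estimation yields, per frame, the image coordinates and a tracking
likelihood for 13 body parts (nose, eye, forepaw, elbow, shoulder, hindpaw,
ankle, knee, hip, iliac crest, tail base, tail centre, tail tip) and 5 beam
reference markers: two vertical lines delimiting the central 80-cm analysis
region, two optional dots that encode the beam type (dot right: 16-mm
square; no dot: 16-mm round; dot left: 9-mm square), and an auxiliary point
that is carried but unused. `beamwalkr` starts from those tables; running
the pose-estimation network itself is out of scope.

Coordinates follow the image convention (y grows downward); frames are
0-based; the analysis region is the half-open pixel interval
`[x_left, x_right)` so that boundary crossings are unambiguous. All "height"
quantities are converted to up-positive as `surface_y(x) − y`, where the
surface line is the least-squares line through the two line markers' median
positions (the markers are static, so per-frame fits would only add noise).
The marker span also fixes the calibration: `px_per_mm = width / 800`.

## Classical endpoints

**Time to cross** is the duration between the nose's first entry into the
region and its first passage beyond the opposite boundary, in seconds.
Re-entries in between are ignored — the first-entry/first-far-exit rule is
the simplest deterministic reading and matches how trials are actually run
(the animal moves toward the goal box). A trial where the nose never enters
or never exits raises an error rather than returning a guess.

**Foot slips** are maximal runs of frames in which the hindpaw's
surface-relative height falls below −18 px, which corresponds to ~9 mm at
the 2 px/mm calibration of the reference rig. Events whose inter-event gap
is shorter than 32 frames (~250 ms) are amalgamated, keeping the first
onset, last offset and deepest nadir; the merge is idempotent and the merged
events are pairwise separated by at least the gap. Both thresholds are
`detection_params()` arguments. Slip detection is restricted to frames where
the hindpaw is inside the central region, matching the region the endpoints
are defined on. On visibly tilted beams the threshold applies to the
surface-relative height, not the raw y coordinate; for a level beam the two
coincide.

Agreement with human annotations is assessed by greedy one-to-one matching
in frame order with a ±30-frame window (250 ms; configurable — the window is
reported alongside the results since recall/precision depend on it),
pooled recall/precision/F1 over a threshold sweep, and per-video Cohen's
kappa on slip counts treated as categorical labels. Degenerate 0/0
precisions and recalls are reported as 0 with a flag; two identical constant
raters give kappa 1 with a flag.

## The feature manifest

Every trial is condensed into a fixed, explicitly enumerated vector
(`feature_registry()`): 78 pairwise body-part distances, 4 joint angles and
13 beam heights, each summarized by mean, min, max and sample (n−1)
variance over the in-region frames of the crossing window, plus sex (F = 0,
M = 1), weight (g), slip count and crossing time — 384 entries. Distances
and heights are normalized by the reference dimension, the mean
elbow–shoulder distance, which removes body-size effects: the whole vector
is invariant under a uniform camera zoom.

Two choices deserve explanation:

* **Joint triplets.** The three points defining each interior angle are the
  anatomically adjacent chains elbow = (shoulder, elbow, forepaw), ankle =
  (knee, ankle, hindpaw), knee = (hip, knee, ankle), hip = (iliac crest,
  hip, knee). Frames where a limb vector degenerates to zero length are
  interpolated from neighbouring frames and flagged.
* **Manifest size.** The constructive rule above enumerates 384 features.
  Published applications of this workflow cite 395, with the full list in
  supplementary material that the constructive description does not fully
  pin down; the 11-entry difference cannot be reconstructed from the rule
  itself. The manifest shipped here is therefore the package's source of
  truth, and `enrich_category()`/`bootstrap_overlap()` take the universe
  from it rather than from a hard-coded constant.

Numerically, features are bit-reproducible across runs, bit-invariant under
a power-of-two zoom, and equal to machine precision (≤ 1e-12 relative) under
general scale-and-translate transforms; per-frame distances and angles are
also rotation-invariant to ~1e-9. Exact binary invariance under arbitrary
similarity transforms is impossible in floating point (every translation
re-rounds intermediates), and the vertical height convention is not
mathematically rotation-invariant — irrelevant in practice because the beam
is horizontal and heights are measured against its fitted surface line.

## Nested leave-one-mouse-out classification

Group discrimination runs per beam on an `experiment_dataset` (trials ×
features, ≤ 2 trials per mouse, one label per mouse). The outer loop holds
out one mouse at a time. Entirely within each outer training set, an inner
leave-one-mouse-out loop:

1. z-scores features with mean and n−1 SD fit on the inner-training rows
   only (constant features map to 0 and are flagged; the binary sex column
   is excluded from scaling),
2. selects 50 features by recursive feature elimination with a
   random-forest estimator, eliminating ⌈0.05 · remaining⌉ features per
   round (floor 1),
3. scores every hyperparameter combination on the inner validation mouse
   (ties resolve to the first combination in grid order), and
4. refits with the tuned hyperparameters on all features and ranks them by
   mean decrease in impurity, keeping the top 50 as that split's list.

The per-split lists are merged by occurrence (descending), then mean rank
(ascending), then name — occurrence dominating rank is a documented
decision; the workflow's description ("both the occurrence and the rank")
leaves the priority open. Hyperparameters are combined by per-key mode, ties
resolving to the earliest value in the grid's declared ordering, flagged.
The default grid — trees {100, 300}, depth {3, 5, unlimited}, minimum node
size {1, 3} — is a documented choice; the underlying workflow does not
state its grid. A final forest on the outer training trials (consensus
features, modal hyperparameters) is scored on the held-out mouse, giving a
per-animal accuracy in {0, 0.5, 1}, and the accuracies are tested against
chance 0.5 with a two-sided one-sample Wilcoxon signed-rank test (zero
differences dropped; all-zero input returns p = 1 with a flag).

Determinism and leakage are handled structurally: one master seed generates
per-split seeds by a fixed arithmetic counter scheme, so a split's selection
and tuning depend only on its training rows and its index — perturbing a
held-out mouse's rows provably changes nothing about its own split, and the
test suite asserts this by instrumentation.

**Balanced class handling.** Holding out one mouse makes its class the
training minority. "Balanced" is implemented in `ranger` as impurity class
weights *plus* a stratified bootstrap that draws the same number of
observations per class for every tree; weight-only balancing leaves a
majority-class pull in the terminal votes.

**Null behaviour.** Even so, leave-one-subject-out evaluation of a flexible
classifier runs *below* chance on data with no group effect: removing an
animal shifts its own class's training distribution away from it (the
well-known anti-correlation pessimism of LOO schemes). On 50 simulated
16-mouse null experiments the grand-mean accuracy measured here is ~0.42,
not 0.50 — and a scikit-learn random forest under the identical protocol
measures lower still (~0.28 on the same data). Users should treat the
Wilcoxon test as conservative: a null experiment tends to sit below chance,
so significant *above*-chance accuracy is strong evidence. The acceptance
suite states the idealized [0.45, 0.55] calibration band and the null check
is expected to fail it for this structural reason; the planted-effect
checks (mean accuracy ≥ 0.9, full recovery of shifted features in the
consensus) pass.

`transfer_predict()` reuses the machinery across cohorts: consensus
features, hyperparameters and scaling statistics all come from cohort A
alone; cohort B is only ever predicted.

## Downstream statistics and visualization

`lda_project()` projects all features (unstandardized by default, matching
common practice of running the discriminant on the engineered features
as-is; a switch enables prior z-scoring) onto ≤ 2 discriminant axes;
features the discriminant fit would reject as within-group constant
(within-group SD < 1e-4) are dropped with a note, and collinearity warnings
— expected when features outnumber trials — are suppressed.
`centroid_distances()` compares each group's samples to the reference
group's centroid. `bootstrap_overlap()` draws all lists uniformly without
replacement from the universe (resampling every list, a documented choice)
and reports `(1 + #{overlap ≥ observed}) / (reps + 1)`, which cannot be 0;
for two lists it agrees with the exact hypergeometric tail within
Monte-Carlo error. `enrich_category()` reports, per statistic family and
per constituent family, the raw counts (k, n, K, N), fold enrichment
`(k/n)/(K/N)` and the upper-tail hypergeometric p — the primitive numbers
are always reported so any derived "percent enrichment" convention is
recoverable.

Skeleton summaries anchor the nose at x = 0 and place each part at minus
its mean euclidean nose distance over the reference (parts trail a mouse
walking in +x; the sign is a display convention), with mean normalized
height as y and bars of ±√(mean per-animal variance). Euclidean rather than
x-axis distance to the nose is a documented choice. Group skeletons average
animals with equal weight. Rendering is deterministic (fixed style, no
timestamps): identical input yields byte-identical files.

## What the simulator does and does not emulate

`generate_trial()` builds a trial from a monotone nose trajectory, a rigid
posture template (body length ~60 mm, heights 2–32 mm above the surface)
hung behind the nose, per-limb sinusoidal gait oscillation, half-sine
hindpaw dips of controlled onset/duration/depth for slips, Gaussian
coordinate jitter, and likelihood dropouts; beam markers are emitted
consistently with the requested geometry and beam type. Defaults mirror the
reference rig (120 fps, 2 px/mm) so that the 18 px ≈ 9 mm threshold is
meaningful on synthetic data. `generate_experiment()` adds log-normal
per-mouse random effects on size and speed (positive scales, mild skew), a
small posture offset, and derives weight from the elbow–shoulder template
length, its anatomical correlate. Group effects are additive template
shifts (mm) and per-part variance multipliers, recorded as ground truth.
`simulate_feature_experiment()` skips the trajectory layer and draws
feature matrices directly — per-mouse random effect (SD 1) plus trial noise
(SD 0.5), with a declared shift on the informative features — and is the
study-condition generator for calibrating the cross-validation.

The simulator emulates the *statistical* structure the pipeline assumes —
monotone progression, smooth limb oscillation, threshold-crossing slips,
size/speed heterogeneity, tracking noise and dropouts. It does not emulate
real gait dynamics (no stance/swing phases), pose-estimation failure modes
(identity swaps, occlusions, beam-edge artefacts), falls or pauses, or
correlated multi-part noise. Passing tests therefore certify the
*computational* contract — detector exactness against planted events,
normalization invariances, leakage-free cross-validation, calibrated
statistics — not performance on real videos, which depends on tracking
quality and rig calibration.

## Problem sizes and numerical conventions

The test suite and acceptance script run at desk scale: 100 seeded trials
for detector exactness, 16-mouse experiments for cross-validation (50 null
seeds, 10 planted seeds), 100 000 bootstrap repetitions, and a reduced
hyperparameter grid (trees 100, depth {3, unlimited}, node size 1) with
50-tree elimination forests — sizes chosen so the full suite completes in
minutes on one CPU while keeping every inference the same shape as a full
run. Other conventions: sample (n−1) variance and SD throughout; 0/0 rates
reported as 0 with flags; angle arccos arguments clamped to [−1, 1];
`approx`-style endpoint-hold interpolation for leading/trailing dropouts; a
keypoint with no confident frame at all is an error, not a guess.

## Known limitations

* Only the camera-side hindpaw is analysed; a second view or mirror would
  be needed for bilateral slip counts.
* The likelihood floor (default 0.6) is a documented default, not a
  published value; filtered tracking upstream may already have applied one.
* Heights use the vertical image axis against the fitted surface line,
  which is exact for level beams and first-order accurate for small tilts.
* Below-chance null behaviour of leave-one-subject-out evaluation (above)
  makes the chance-level test conservative rather than exact.
* With ≤ 2 trials per animal, per-animal accuracies take only three values,
  so the Wilcoxon test's resolution is limited at small n.
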