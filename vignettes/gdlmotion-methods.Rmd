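---
title: "Key-frame rule classification of motion-capture streams: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Key-frame rule classification of motion-capture streams: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gdlmotion)
```

## The problem

Sport-technique and rehabilitation-exercise analysis works from motion-capture
(MoCap) skeleton streams: per-frame 3D positions of a fixed set of tracked
body joints (20 joints for Kinect-v1-class devices, 25 for Kinect v2, or
whatever a high-end optical system exports via BVH).  Coaches and
physiotherapists need two things from such streams: *kinematic features*
(joint angles and their derivatives, without regard to forces) and
*recognition* of when a technique or exercise repetition was performed.

`gdlmotion` implements the Gesture Description Language (GDL) family of
methods for this task:

1. **Features.** Typed, declarative per-frame features over joint positions —
   logical, numeric, or 3D-vector valued — built from vector algebra
   (sum, difference, scaling, dot and cross products, norms) and the
   unsigned angle between two vectors.
2. **Key-frame rules.** A *key frame* is a characteristic pose, defined by a
   boolean rule over the current feature values (e.g.
   `A1 > 50 and A1 < 110 and A2 > 135`).
3. **Sequential classification.** An *action* is an ordered sequence of key
   frames with time restrictions.  Incoming frames are pushed onto a bounded,
   time-ordered **memory stack**; an action fires when its key frames appear
   in order within the restrictions, with the newest frame satisfying the
   final key frame.
4. **R-GDL training.** Key frames need not be hand-written: pooling exemplar
   recordings in feature space and clustering with k-means discovers the key
   poses; interval rules synthesized around the cluster centroids yield an
   executable action definition.

## The angle features

The worked feature set (`builtin_hiza_geri_features()`) describes a knee kick
(Hiza-Geri) on the 25-joint topology.  Five direction vectors are built from
joint positions — v1 the right thigh (hip to knee), v2 the torso axis (spine
base to spine shoulder), v3 the right shin (knee to ankle), v4 the left
thigh, v5 the global vertical (0, 1, 0) — and six features are the pairwise
unsigned angles, in degrees:

A1 = ∠(v1, v2), A2 = ∠(v3, v2), A3 = ∠(v4, v2),
A4 = ∠(v1, v5), A5 = ∠(v3, v5), A6 = ∠(v4, v5).

`angle()` is contractually arccos(a·b / |a||b|), clamped to [0°, 180°]; it is
computed internally as atan2(|a×b|, a·b), which is mathematically identical
and better conditioned near 0° and 180°.  Degrees were chosen because the
thresholds practitioners write (a knee at "90 degrees") are degrees.

**Invariance.**  A1–A3 compare body segments with the torso axis and are
invariant under *any* rigid transform (rotation + translation) of the
skeleton.  A4–A6 reference the gravity vertical, so their invariance class is
the gravity-preserving rigid transforms: rotations about the vertical axis
(heading) plus translations.  This is the meaningful class for human motion —
a recording should not depend on where the subject stands or which way they
face, but tilting the subject relative to gravity *is* a different pose.  The
test suite asserts both classes at 1e-9°.

## Sequence matching semantics

The memory stack retains `capacity` seconds of history (default: largest
action `max_span` + 1 s, so no witness is ever evicted prematurely), evicting
from the oldest end only.  For an action with key frames K1…Kk:

* a classification fires iff the newest entry satisfies Kk and there are
  entries e1 ≤ e2 ≤ … ≤ ek (ek = newest) with ei satisfying Ki, consecutive
  gaps ≤ `max_gap`, and total span ≤ `max_span`;
* the same frame may witness two consecutive key frames (a pose can meet
  both definitions at once); `strict = TRUE` forbids this;
* among multiple witnesses, the reported one has the latest-possible earlier
  key-frame times.  This is found by depth-first search exploring candidates
  newest-first; plain greedy-latest selection would be wrong, because taking
  the latest middle key frame can push the preceding key frame out of its
  `max_gap` window while an earlier middle witness succeeds.  The test suite
  checks presence/absence *and* the reported witness against exhaustive
  enumeration over all index tuples on 1000 random instances;
* after an event, a refractory period equal to `max_gap` suppresses duplicate
  triggers from consecutive frames satisfying the final key frame — one
  performed repetition yields one event.

Both time restrictions are mandatory and deliberately per-action: `max_gap`
bounds the transition time between consecutive key poses, `max_span` bounds
the whole performance.  Either can be set large to disable it.  A
three-key-frame witness needs its middle frame within `max_gap` of *both*
neighbours' satisfying frames, so `max_gap` must be of the order of one pose
hold plus one transition — the shipped kick action uses 1.0 s for the 0.5 s
hold / 0.5 s transition tempo of the built-in script, and `max_span` 2.5 s,
roughly twice the observed 1.2 s first-to-last key-frame span of one kick.
These are documented tunables, not calibrated constants.

The engine is causal: classifying frame-by-frame (`engine_step()`) and in
batch (`classify_stream()`) produce identical events and timelines; the batch
path merely vectorises feature and rule evaluation over the stream.  Each
frame also receives a timeline label per action: the highest-index satisfied
key frame, or "N" when none is satisfied (later phases supersede earlier ones
when a frame satisfies several).

## The synthetic-motion generator

`generate_motion()` produces labelled streams by linear interpolation of full
key poses at a fixed rate, with i.i.d. Gaussian positional noise per joint
coordinate.  It emulates the shape of exercise recordings — held key poses,
transitions, repetitions — not human dynamics: no inertia, no anthropometric
variation, no sensor-specific artefacts (occlusion, jitter correlation).
Passing tests therefore demonstrate correctness of the algorithms against
known ground truth, not field performance on real recordings.

Design choices worth stating:

* **Noise level.** The default `noise_sigma_pos = 0.015` m corresponds to
  roughly 3° of direction noise on a 0.4 m limb (σ_angle ≈ √2·σ_pos/L),
  a realistic magnitude for depth-camera joint estimates.
* **Pose geometry.** The built-in kick poses keep every planted angle inside
  [30°, 170°].  An unsigned angle at exactly 180° would fold symmetric noise
  (the measured angle becomes 180° minus a Rayleigh deviate), biasing pose
  means by several degrees; a slight forward torso lean (10°) and leg tilts
  avoid the degeneracy and make the torso axis distinct from the vertical.
* **Interpolation.** Linear interpolation of joint positions slightly
  shortens limbs mid-transition (chord of the arc), which *amplifies*
  angular noise there — a property to keep in mind when rules sit close to
  transition trajectories.
* **Repetition structure.** Between repetitions the built-in kick script
  returns to the neutral stance over 6 s, emulating an athlete resetting.
  The return necessarily retraces the pose space backwards (continuity), so
  rules that must not fire on the recovery need a discriminating feature:
  the shipped kf2 requires A2 > 135°, met while the shin hangs during the
  knee raise but not during the recovery, when thigh and shin drop together.

## R-GDL training choices

* **k is a user input**, default 3 (the classic knee-kick definition has
  three key frames).  `pca_project()` supports visual inspection of the
  cluster structure; no automatic k selection is silently applied.
* **Standardization.** Feature columns are standardized (zero mean, unit
  spread) before k-means and PCA; zero-spread columns pass through with unit
  scale.  Mixed-magnitude features would otherwise dominate the metric.
* **k-means.** `stats::kmeans`, squared-Euclidean objective, fixed seed,
  10 random restarts, plus one deterministic start at the phase-bin means
  (key frames are temporal, so means of early/middle/late frames are strong
  initial centroids); the best objective wins.  Identical inputs and seed
  give identical models.
* **Temporal order** of clusters is the order of the mean normalized phase
  (time within exemplar scaled to [0, 1]) of member frames.
* **Tolerances.** Rule intervals are centroid ± 3 standard deviations of the
  member rows per feature, floored at 5° — wide enough to cover members
  without ballooning into neighbouring clusters.
* **Time restrictions** are estimated from exemplar timing when not given:
  the 95th percentile of observed consecutive-cluster gaps and first-to-last
  spans (per exemplar, mean member timestamps per cluster), times a 1.5
  safety factor.
* **Only numeric features train**; logical features are rule outputs, not
  inputs.  Frames from all exemplars are pooled before clustering.

Under the validation conditions used in the tests (20 exemplars per run,
poses separated by ≥ 30° in at least two features, σ ≈ 3° noise, 1 s holds,
0.1 s transitions, 30 Hz), recovered centroids sit within 2° of the planted
pose angles: the residual is dominated by the few interpolated transition
frames absorbed into each cluster (~1°), not by noise.  Negatives for the
closed-loop test are generated with the key-pose *order reversed* — the
phase structure is destroyed while the per-frame pose content is preserved,
which is the correct falsification target for an order-sensitive classifier.
(Shuffling individual frames would scatter all three key poses uniformly in
time and any ordered triple would appear within almost any time restriction;
that negative is unachievable by construction for any classifier of this
family.)

## Numerical and degenerate-input conventions

* Zero-length vectors inside `angle()` raise an error naming the offending
  operand on the single-frame path; on the stream path the frame's features
  become `NA`, the frame is labelled "N", a warning is logged, and the
  stream continues.
* Timestamps must be strictly increasing on every construction path; the
  memory stack additionally rejects regressions at push time.
* Streams are written with `%.17g` so doubles round-trip exactly; config
  documents (YAML) write with fixed 15-digit precision so write → read →
  write is byte-identical.
* PCA component signs follow a deterministic convention (largest-magnitude
  loading positive); constant columns are dropped with a warning.
* All randomness (generator noise, k-means restarts) flows from explicit
  integer seeds; generation restores the caller's RNG state.

## Problem sizes used in validation

The shipped test-suite and acceptance script sizes are: 1000 random vector
pairs for the angle oracle; 100 random transforms for invariance; 1000
random matcher instances (stacks ≤ 50 entries, sequences ≤ 5 key frames)
against exhaustive enumeration; one 10-repetition kick stream (~2400 frames)
for end-to-end detection; 20 training runs of 20 exemplars each (~1920
pooled frames per run) with 5 held-out positives and 5 reversed negatives
per run; and processing-time measurements at {100, 200, 500, 1000, 2000,
5000, 10000, 20000} frames for the linearity statistic (R² of total time vs
frame count; absolute per-frame milliseconds are reported but are
hardware-dependent).

## Known limitations

* Rule matching is exact boolean satisfaction — no probabilistic scoring,
  no partial credit; borderline poses flicker at rule boundaries unless the
  rule author (or the tolerance synthesis) leaves hysteresis margins.
* Cyclic exercises genuinely contain reversed key-frame sequences in their
  recovery phases; discriminating rules (or asymmetric feature choices) are
  needed when the reverse motion must not count.
* Forward references between features, and rules referencing other rules'
  conclusions, are rejected by design.
* BVH import supports the standard single-root HIERARCHY/MOTION dialect
  with position/rotation channels in any declared order; orientation
  (quaternion) streams are not consumed — all features derive from
  positions.
* The trainer assumes every exemplar contains exactly one performance;
  multi-repetition exemplars blur the phase ordering (pool single-repetition
  cuts instead).
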