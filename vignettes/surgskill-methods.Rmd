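---
title: "Assessing surgical skill from instrument kinematics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing surgical skill from instrument kinematics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surgskill)
```

## The problem

Structured rating scales — GEARS (six subcategories) and OSATS (seven
subcategories), each scored 1–5 — are the standard way surgeons assess
technical skill from operative video, but human review is slow and raters
disagree. `surgskill` implements an automated two-stage pipeline:

1. **Segmentation.** An attention-augmented fully convolutional
   encoder–decoder labels each video frame pixel with one of eight classes:
   background plus seven instrument parts (upper flexion, abduction and
   grasper/cutter for each arm, and the needle).
2. **Scoring.** Each mask is reduced to 21 kinematic scalars — centroid
   `x`, centroid `y` and pixel area for each part class, normalized to
   `[0, 1]` — and the resulting variable-length T×21 sequence is mapped by
   a multi-task temporal convolutional network (mtCNN) to all thirteen
   subcategory scores plus the surgical task segment (cut / recon /
   bolster).

Because surgical video cannot be redistributed, the package ships a
synthetic-data module that emulates both stages' inputs with known ground
truth, so every component is testable end to end.

## The segmentation network

`seg_config()` describes a U-shaped network with five encoder blocks
(3×3 convolution, ReLU, 2×2 max pooling), three bottleneck blocks, and
five decoder blocks (2× nearest-neighbour upsampling, skip merge, 3×3
convolution). Two attention mechanisms are placed exactly where they act
in the reference design, with internals chosen for testability since the
cited building blocks are not specified to the equation level:

* **Global attention** — a single-head spatial self-attention layer over
  the bottleneck feature map (tokens = bottleneck pixels), with a residual
  connection.
* **Cross attention** — in the deepest decoder blocks (default: the first
  two, where token counts are small), decoder features form queries that
  attend over the skip-connection features; the attended skip replaces the
  plain skip in the merge. This lets the decoder reweight encoder evidence
  spatially.

Training minimizes per-pixel cross-entropy (the reference work does not
name its segmentation loss) with Adam, logging one batch-IoU per optimizer
step and checkpointing whenever held-out IoU improves. Augmentation draws
one similarity transform per presentation (scale 0.9–1.1, rotation ±15°,
shift ±10% by default) and applies it identically to frame and mask with
nearest-neighbour resampling; evaluation paths never augment. Enhancement
workflows — labeling extra frames where a trained model produces false
positives and appending them to the training list — are supported by the
plain-list dataset interface.

IoU averages per-class intersection-over-union over the classes present in
either mask; classes absent from both are excluded rather than scored 1,
so negative frames cannot inflate results.

## The scoring network

`score_config()` builds the mtCNN: a shared trunk of three 1D convolutions
(kernel 5, stride 1, replicate padding) over the feature sequence, a
parallel attention pathway that produces normalized per-timestep weights,
and a weighted temporal average that collapses any sequence length to a
fixed-size summary feeding fourteen small MLP heads (thirteen 5-way
ordinal classifiers, one 3-way task classifier). The trunk and pooling are
shared across heads — the multi-task structure — while heads are
task-specific.

The input is lifted before the first convolution: areas are rescaled to
roughly percent-of-image units, and the 21 raw channels are augmented with
their scaled first temporal differences and the per-class speed
magnitudes. The lift is a fixed, parameter-free layer; it exists because
the kinematic signal (frame-to-frame displacement, ~10⁻²–10⁻³ image
units) is two orders of magnitude smaller than the absolute positions the
raw features carry, and a magnitude-balanced input makes optimization of
the small network well behaved.

Three attention variants share the trunk and differ only in pooling:

* **WG (weight gated)** — 1D convolutions on the lifted input followed by
  a temporal softmax produce the weight vectors. Replicate padding makes a
  constant sequence produce exactly uniform weights.
* **SA (self-attention)** — weight vectors computed from the trunk
  features via a tanh bottleneck and temporal softmax (a structured
  self-attentive embedding).
* **DP (direct self-attention pooling)** — learned queries attend over
  keys/values projected from trunk features; the attention output replaces
  the weighted average. Output size is sequence-length invariant for all
  variants.

Sequences shorter than `min_length` (default 16) are left-padded with
zeros and the padded positions masked out of every attention softmax.
Ties in the argmax label rule break toward the lower score.

## Losses

Two subcategory losses are provided; the task head always uses
cross-entropy because its three classes are unordered.

The **weighted-kappa loss** treats each head's batch as a rating pair:
`O[i, j]` collects the predicted probability mass on level `j` for samples
whose true level is `i` (a differentiable surrogate; with one-hot
predictions it equals the hard count matrix), `E` is the outer product of
`O`'s marginals rescaled to the same total, and `w[i, j] = |i−j|^k /
(N−1)^k` with `N = 5`, `k = 1`. Then

&kappa; = 1 − &Sigma; wO ⁄ &Sigma; wE,  loss = log(1 − &kappa; + &epsilon;).

The absolute value in `w` is deliberate: a signed `(i−j)^k` at odd `k`
would produce negative "penalties" and break the κ ≤ 1 bound, so the
standard linear weighting is used. κ is computed per mini-batch per head
(it is undefined for a single sample); the analytic gradient through the
soft observed matrix is verified against finite differences in the test
suite. Hard counts are always used for reported metrics.

## Evaluation protocol

Splits and bootstrap resampling operate on surgeries, never on frames or
sequences, so no surgery contributes to both sides. `run_bootstrap()`
draws surgeries with replacement as the training multiset, evaluates on
the out-of-bag surgeries, redraws the rare all-in-bag rounds, and combines
the two accuracies with the classical estimator `0.368·train +
0.632·oob` (the named rule's formula; 0.632 = 1 − 1/e is the large-n
probability that an item enters a resample — `bootstrap_distinct_fraction()`
verifies this empirically). `subcategory_report()` summarizes per-subcategory
accuracy and signed-residual quartiles (predicted − true; positive means the
model rates skill above the rater) in box-plot-ready form, with overall
`mean ± sd` strings. The reference protocol runs over 1000 rounds; the
default here is 50, suited to a desktop — rounds are configurable.

## The synthetic data generator

**Scenes.** Part classes are drawn as elongated capsules with distinct
hues plus shared specular noise, on a smoothly textured gray background;
classes are separable but not trivially so, letting a small segmenter
reach high IoU in minutes while exercising real multi-class logic. Regions
are placed disjointly; placement failure raises an error naming the class.
Empty `parts_present` yields negative examples. What this does *not*
emulate: tissue appearance, blood, occlusion, motion blur, or deformable
instruments — a high synthetic IoU therefore demonstrates the machinery,
not clinical-grade segmentation.

**Trajectories.** Each case draws a regime (cut / recon / bolster) and
case-level multipliers: speed scale (disjoint ranges for cut vs bolster),
an AR(1) smoothing coefficient controlling jerk, an idle-frame rate, a
left/right speed ratio, and a log-area AR(1) sd. Arm positions follow
reflected smoothed random walks (classes 1–3 ride the left hand, 4–6 the
right, the needle appears only in recon). Observed sequences add a
measurement model chosen to mimic segmentation error: pose-persistent
AR(1) centroid bias plus small independent flicker for positions, and
multiplicative area error (boundary mistakes scale with region size).

**The score rule.** Five statistics — mean speed, jerk (mean |second
difference|), idle fraction (speed below an absolute 0.004 units/frame
threshold), left/right mean-speed difference, and mean absolute area
change — are each time-averages of local quantities, hence recoverable by
temporal convolution plus attention pooling. `calibrate_score_rule()`
fixes, once, each statistic's quintile cut-points under the default spec
(balanced labels) and maps every subcategory to one statistic with a
direction; the task rule is needle-presence then a speed threshold. Labels
are always computed from the noise-free latent trajectory, making the
generator a parameter-recovery benchmark: the scorer sees only the noisy
sequence and must recover rule-consistent scores.

## Numerical choices and problem sizes

* Adam with decoupled weight decay (default 10⁻³ for the scorer); step
  learning-rate decay (×1/3 at 60%, ×1/10 at 85% of epochs).
* Scorer training augments by random contiguous temporal crops (50–100%
  of the sequence); the rule statistics are time averages, so crops are
  label-preserving to first order and suppress memorization of individual
  sequences.
* Segmentation reference runs in the tests use 200 training scenes of
  64×64 pixels, base width 8 and 6 epochs; scoring runs use 600 training
  sequences of 40–120 frames with trunk width 32 and 40–60 epochs. These
  sizes were chosen as the smallest at which both stages exhibit their
  qualitative behaviour clearly on a single desktop core.
* All generators and builders are pure functions of (spec, seed): RNG
  state is scoped, restored after use, and sub-seeds are derived
  deterministically from master seeds.

## Known limitations

* The weighted-kappa loss optimizes agreement, not exactness: off-by-one
  predictions are cheap for it, so κ-trained models trail cross-entropy
  models on exact-match accuracy (the reference study observed the same
  ordering on real surgery). Its gradient also steepens sharply as κ→1,
  making late training noisier than cross-entropy.
* Attention-block internals follow the stated placement but are this
  package's own minimal constructions; parameter-count comparisons against
  other implementations are out of scope.
* The synthetic benchmark demonstrates recoverability and protocol
  correctness; none of its accuracies transfer to real surgical video.
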