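---
title: "Modulatory feedback and attentional figure-ground segmentation: model and methods"
author: "segnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modulatory feedback and attentional figure-ground segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`segnet` implements a two-pathway model of the primate ventral stream for
object classification and attention-conditioned scene segmentation.

The **feedforward pathway** is driving: a 56x56 grayscale image passes
through three model areas (V1m: 20 features at 56x56, V2m: 50 at 28x28,
V4m: 100 at 14x14), each consisting of three convolutional blocks
(3x3 convolution, batch normalization, rectifier) with identity skip
connections, joined by stride-2 2x2 convolutions that halve the
resolution. The down-sampled V4m output (100x7x7) feeds a fully
connected layer (ITm, 500 units) and a 12-unit class layer (FCm) with
independent per-class sigmoids: several object classes can be present at
once, so the output is multi-label, not a distribution. Attention has
no influence on this pathway.

The **feedback pathway** is modulatory. A one-hot attention vector is
multiplied elementwise with the FCm class scores; a driving head
(a fully connected mirror of FCm to ITm, a transposed-convolution layer
producing a 100x7x7 tensor, concatenation with the feedforward 100x7x7
tensor into 200x7x7, and a 1x1 fusion convolution back to 100x7x7)
produces the top-level feedback drive. From there, every feedforward
unit in V4m, V2m and V1m has a mirrored feedback unit — the cortical
column analogy — obeying

\[ b_i = \max(0,\; a_i\,(z_{i+1} + \beta_i)), \qquad c_i = b_i - a_i, \]

where \(a_i \ge 0\) is the feedforward activity of the same unit,
\(z_{i+1}\) the (signed) drive arriving from the next-higher feedback
layer, and \(\beta_i\) a learned offset. Feedback therefore *scales*
feedforward activity and can never activate a silent unit — the defining
property of modulatory connections. The propagated signal is the
difference \(c = b - a\): positive where feedback enhances a unit,
negative where it suppresses it, and exactly zero wherever the unit is
silent. Between areas, \(z\) is produced by a learned stride-2 2x2
transposed convolution (the resolution must double); between mirrored
layers within an area, by a learned 1x1 convolution. A learned 1x1
read-out of the lowest V1m mirror, followed by a sigmoid, yields the
56x56 segmentation map.

### Why the read-out uses c, not b

The read-out source is configurable (`seg_config(readout_source=)`), and
the default is the feedback signal `c`. The choice matters because the
segmentation loss deliberately ignores pure-texture background pixels
(see below): nothing ever penalizes the map on the background. `b`
carries the feedforward response multiplicatively
(\(b \approx a\beta\) wherever no feedback arrives), so a read-out of
`b` has no architectural reason to stay dark on the background and, in
practice, floods it. `c`, by contrast, is zero wherever no feedback
arrives and is the network's own comparison between feedback and
feedforward activity — a segmentation signal by construction. With a
negative read-out bias the background stays dark although it is never
supervised, which is exactly the behavior the model family is meant to
explain. Time-course analyses still record `b` (the feedback *units*),
matching the quantity plotted in neurophysiology-style figures.

### Other architectural choices

* Convolution kernels within areas are 3x3 with same-padding; the small
  stated receptive fields (2x2 pixels in V1m) make larger kernels
  implausible.
* Each conv block's skip connection is an identity addition (a learned
  1x1 projection where channel counts change, i.e. at the area input).
* \(\beta\) is learned per feature map of each mirrored layer
  (`beta_granularity = "channel"`; a scalar per layer is available).
  \(\beta\) is initialized at 1 so that an untrained feedback pathway
  reproduces the feedforward activity (\(z=0 \Rightarrow b=a,\ c=0\)) —
  a neutral starting point for optimization.
* Batch normalization uses batch statistics during phase-1 training and
  running statistics everywhere else, so inference and simulation are
  deterministic.

## Stimuli

`generate_dataset()` builds SegMNIST-style scenes: 56x56 canvases with an
oriented line-element background texture and one to three objects from
twelve classes (texture square, texture rectangle, digits 0-9), each
with a multi-hot label vector and pixel-accurate per-class masks.

* **Textures** are fields of short anti-aliased bars (length 5 px, width
  1.5 px, ~7 elements per 100 px², placed on a jittered grid). Density,
  bar geometry and the use of oriented line elements emulate the dense
  texture-segregation displays of the monkey experiments this model
  family addresses. Figures are defined *only* by the orientation of
  their texture: mean luminance of figure and ground regions differs by
  less than 0.05 (the camouflage property, asserted by tests).
* **Orientations** are drawn from the four axes {0°, 45°, 90°, 135°},
  with figure texture orthogonal to the background — the standard
  convention of texture-segregation experiments (e.g. 45° figures on
  135° grounds). A continuous orientation variant was considered and
  rejected: it does not match the cited displays.
* **Figures**: squares have sides uniform in 14-28 px; rectangles use
  h in 14-18 px with aspect ratio uniform in [1.5, 2] (capped at 28 px),
  so that the two shape classes are visually distinct categories rather
  than a near-continuum; outline rotation is uniform in [0°, 180°).
* **Digits** are procedural stroke-skeleton glyphs (28x28, per-class
  skeleton with seeded thickness/slant/position jitter), scaled by a
  factor uniform in [0.75, 1.5]; strokes overwrite the texture and the
  ground-truth mask is exactly the stroke pixels. Real MNIST bitmaps can
  be substituted via `mnist_dir` (standard IDX files); nothing in the
  package requires a download.
* **Placement** is uniform with rejection: object masks may not overlap;
  a placement is resampled up to 100 times, and a whole scene up to 25
  times (crowded scenes with several large figures can be infeasible).
* **Region maps** (`region_map()`) assign figure / edge / ground /
  excluded per pixel: the edge band is the mask dilated minus eroded by
  2 px (box structuring element) — about one V1m receptive field on each
  side of the contour; pixels of other objects are excluded from every
  analysis.

What the generator does *not* emulate: luminance or contrast variation
between elements, occlusion, natural images, color. Passing tests on
these stimuli therefore demonstrate the mechanism (orientation-defined
figure-ground segregation and object-based attention), not performance
on natural scenes.

## Two-phase training

Phase 1 trains the feedforward pathway alone for multi-label
classification: Adam (learning rate 0.001, weight decay 0.0005),
sigmoid + binary cross-entropy on the 12 logits; reference protocol
2,500 epochs at batch 1024. Phase 2 freezes every feedforward parameter
(verified bit-exactly) and trains the feedback pathway for
attention-conditioned segmentation: for each example an attended class
is sampled uniformly among the classes present, the target map is 1 on
that class's mask and 0 elsewhere, and the pixel-wise BCE ignores
background pixels; reference protocol 2,500 epochs at batch 256.

"Background" in the ignore rule means pixels outside *every* object
(`ignore_policy = "texture_background"`): pixels of non-attended objects
are kept as 0-targets, since they are the only counter-examples that
teach the network to suppress distractor objects. The alternative
reading (ignore everything outside the attended object) is implemented
behind the `all_nonattended` flag but leaves suppression unlearned.
Suppression of the never-supervised texture background is then an
emergent generalization from the suppressed distractor objects — which
is why the background false-labeling rate is a reported metric and not a
trained objective.

Evaluation metrics follow the model family's conventions:

* `classification_abs_error`: per image \(\sum_k |s_k - y_k|\) over the
  12 classes, averaged over images; 0 when everything is classified
  correctly, 12 when nothing is.
* `pixel_abs_error`: mean of \(|m - 1|\) over attended-object pixels
  only (range [0, 1]; background not considered).
* `background_false_rate`: fraction of true-background pixels above
  threshold (default 0.5).

Because the feedforward pathway is frozen in phase 2, its activations
for the training set are precomputed once and reused across epochs when
they fit in memory (`cache_activations`); this changes nothing
numerically.

Initialization of the feedback pathway is data-dependent. The mirror
chain multiplies its drive by the (frozen, trained) feedforward
activity at every one of nine mirrored layers, so a fixed weight scale
either explodes or vanishes geometrically with depth — no single gain
suits all feedforward statistics. At the start of phase 2 the feedback
weight matrices are therefore rescaled in topological order so that
each produced drive has a target standard deviation (0.5) on a
calibration batch, and the read-out produces unit-scale logits
(layer-sequential unit-variance initialization). The modulation
offsets \(\beta\) start at 1 regardless, so the calibrated network
still satisfies \(b \approx a\), \(c \approx 0\) before training.

## Problem sizes used in the shipped checks

The reference protocol (12 classes, 50,000 stimuli, 2,500 epochs per
phase — roughly half a million optimizer steps) is far beyond a
desk-scale run, and its headline scores are not reproduced here. The
package instead ships a scaled-down end-to-end protocol as its own
smoke-scale study: the square/rectangle task, 2,000 generated stimuli
(1,800 train / 200 validation), a narrow model (V1m/V2m/V4m features
4/8/16, ITm 32 — the full-width architecture is asserted separately),
batch 32, and epochs chosen at the loss plateaus observed in pilot runs
(6 for phase 1, 8 for phase 2 in the test suite). The acceptance suite
evaluates this protocol against the reference smoke thresholds
(detection accuracy 0.95, mean IoU 0.7); the limitations section below
explains why pixel-level segmentation precision at this scale stays far
below the full-width reference, which the corresponding checks document
rather than hide. The full 12-class, full-width replication recipe is in
the README. Training/validation splits use a fixed, documented seed;
"cross-validated" in the reference protocol is realized here as a
held-out split, the simplest defensible protocol when fold structure is
unspecified.

## Time-stepped propagation

`run_timecourse()` simulates the recurrent timing of the model without
modeling full recurrence: a single feedforward and a single feedback
pass, unrolled over a directed graph in which every connection transmits
its source's previous-step value once per step (wavefront semantics).
The network is initialized at its response to an i.i.d. uniform
white-noise image matched in mean and variance to the background
textures, with the attention template already active; the stimulus is
switched on at step 0.

Step granularity defaults to one step per between-area connection
(`granularity = "area"`; the three blocks within an area are computed
within the step), reconciling "one connection at a time" with the
coarse per-step time calibration of the reference analyses; a strict
per-layer mode (every convolutional layer its own step) is available.
The default step budget is twice the input-to-V1m-mirror path length
plus 4 margin steps.

Because mirror units are gated by the feedforward activity they share a
column with, the V1m mirror responds in three phases: (1) a
stimulus-driven response as soon as `a` arrives (step 2 at area
granularity); (2) figure-ground modulation when spatially structured
feedback first loops down from V4m's feedforward tensor (before any
class information — the head fuses the feedback drive with the
feedforward 7x7 tensor, which is stimulus-driven from step 4); (3)
attentional modulation last, once class information has traversed
input to FCm and back down. In terms of when information *can* arrive,
the attended-versus-unattended divergence is therefore strictly later
than the figure-ground divergence, which is strictly later than the
first response — the ordering seen in monkey V1. Whether the later
divergences are *measurable* above trace noise depends on how strongly
the feedback pathway has been trained; at smoke scale they can be
orders of magnitude smaller than the stimulus transient (see
Limitations), and the onset detection then reports them as undefined
rather than inventing an ordering. Onsets are always measured relative
to the pre-stimulus state, because the pre-activated attention template
makes the two conditions differ already at initialization.

Region traces record the channel-averaged activity of the V1m mirror's
feedback units `b` per figure/edge/ground region (`record = "c"` and
`"a"` are available), aggregated as mean ± SEM across stimuli.
Figure-ground modulation (FGM) is the figure (or edge) trace minus the
ground trace. Space-time profiles bin pixels by signed Chebyshev
distance to the figure boundary (positive inside; other objects
excluded) and report the per-bin response minus the deep-ground
reference (bins at least 3 px outside). Traces may be up-sampled to 160
points and smoothed with a 3rd-order, 7-sample Savitzky-Golay filter
for display; all statistics are computed on raw step-resolution traces.

## Numerical choices and degenerate inputs

* The engine stores activations as dense `(N*H*W) x C` matrices and
  evaluates convolutions as patch-matrix GEMMs (compiled packing
  kernels); gradients were verified against central finite differences
  at 1e-8 relative error.
* Stable BCE-with-logits (`max(x,0) - xy + log1p(exp(-|x|))`) avoids
  overflow for saturated logits.
* Degenerate inputs raise explicit errors: zero-density textures,
  figures crossing the canvas, clipped glyphs, empty masks, all-ignored
  segmentation losses, non-one-hot attention vectors, non-finite
  losses (training aborts with a diagnostic rather than continuing on
  NaN).
* Determinism: every stochastic step (dataset, initialization,
  shuffling, attended-class sampling, noise images) is governed by an
  explicit seed, and RNG state is restored after seeded sections, so
  identical seeds give byte-identical stimuli, trajectories and traces.
* Ties at the modulation threshold (`a(z+beta) = 0`) propagate a zero
  subgradient, matching the rectifier convention.

## Known limitations

* Single feedforward and feedback pass only; no full recurrence, no
  horizontal connections, no dorsal/thalamic routes (all out of scope by
  design).
* The procedural digit glyphs are a stand-in for MNIST: per-class shape
  variability is far smaller than handwriting; classification of digits
  is correspondingly easier than in the reference setting.
* The smoke-scale model is narrow; quantities that depend on
  representational capacity (for example absolute error rates) are not
  comparable to the full-width reference numbers, and the package makes
  no claim that they are.
* Pixel-precise segmentation is representation-limited at smoke scale.
  Because the figures are camouflaged (luminance-matched, orientation
  defined), per-pixel figure-ground information must be created by the
  classification pretraining — and a few epochs over 1,800 scenes leave
  the frozen feedforward features with only weak pixel-level
  figure-ground signal. The modulatory pathway can only gate what the
  feedforward features carry, so the thresholded maps of the smoke model
  remain coarse however the feedback pathway is trained; the
  corresponding end-to-end acceptance checks report this honestly.
  Reaching the reference behavior requires the full-width pathway and
  reference-scale training.
* Segmentation spatial precision is further limited by the 7x7
  bottleneck of the feedback head; precision recovers through the
  gated, full-resolution mirrors but remains below the reference runs.
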