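---
title: "Characterizing coronary plaque composition in intravascular OCT with a two-pathway cascade CNN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing coronary plaque composition in intravascular OCT with a two-pathway cascade CNN}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(octplaque)
```

## The problem

Intravascular optical coherence tomography (OCT) images the coronary artery
wall at micrometre resolution from a rotating catheter. Each frame is
acquired natively in polar coordinates: one axial depth scan (A-line) per
angular position, stacked into a depth x angle raster; a pullback is the
sequence of frames recorded while the catheter is withdrawn. The
composition of an atherosclerotic plaque — fibrous, calcified or
lipid-rich tissue — determines its stability, and the three components
have recognizable OCT signatures: fibrous tissue is homogeneous and
signal-rich, calcified tissue is signal-poor and uneven with sharply
delineated borders, lipid tissue is signal-poor with diffuse borders.
Reading hundreds of frames per pullback by eye is slow and
observer-dependent, which motivates a fully automatic pixel classifier.

`octplaque` implements such a classifier as a patch-based convolutional
network: the class of a pixel is predicted from the M x M RGB patch
centered on it. Around the classifier sit the stages any practical system
needs — lumen and guidewire segmentation to define the region where
classification is meaningful, class-balanced patch extraction, a cascaded
second stage that conditions on spatial label context, convolutionalized
whole-image inference, and evaluation statistics. Because no clinical OCT
dataset with per-pixel tissue labels is publicly deposited, the package
also ships a synthetic phantom generator with analytic ground truth; every
stage is developed and tested against it.

## Lumen, guidewire and the region of interest

OCT penetrates roughly 1 mm of tissue, so classification is only
meaningful in a band beyond the lumen border. The band is constructed
fully automatically:

* **Lumen contour.** The lumen border is the strongest dark-to-bright
  axial step in the polar frame. `gradient_cost()` scores each pixel with
  the negative axial intensity difference and `dp_min_path()` finds, by
  dynamic programming, the one-depth-per-A-line path of minimum total cost
  subject to a smoothness bound (`max_step`, default 2 pixels per A-line)
  with a closed-contour (periodic) constraint. Exact periodicity is solved
  by restarting the recursion from every anchor row, which is exact but
  quadratic in depth; above a size threshold a column-tripling heuristic is
  used instead. Cost ties are broken toward the smaller depth so results
  are deterministic.
* **Guidewire shadow.** The metal guidewire casts a dark angular band that
  persists across frames. Averaging each A-line over depth and stacking
  frames turns it into a continuous dark stripe across the pullback, which
  the same DP tracer follows (with the angular axis treated as circular).
  The band width is found per frame by scanning outward until the column
  mean recovers above a configurable fraction (default 0.6) of the global
  median, with a fallback half-width of 5% of the A-line count when the
  scan is inconclusive. Lumen depths under the shadow are interpolated
  from the flanking columns.
* **ROI band.** `build_roi()` marks, per non-guidewire A-line, the
  `roi_depth` pixels beyond the contour (default 100 pixels, on the order
  of 1–1.5 mm at typical 15 µm axial sampling; the value is a config
  constant, not re-derived from the resolution). Everything outside is
  background by definition.

## The two-pathway network

The classifier (`twopath_spec()`, `build_network()`) joins two convolution
pathways over the same 33 x 33 x 3 input patch:

* local pathway: 7x7 convolution → 4x4 max pool (stride 1) → 3x3
  convolution → 2x2 max pool (stride 1) → 3x3 convolution;
* global pathway: a single 15x15 convolution with more feature maps than
  the last local layer (defaults 64/64/64 local, 160 global).

Each hidden convolution is followed by a ReLU and a feature-map
normalization `(x − µ)/√(σ² + t)` (`t` defaults to 1e−5). Both pathways
shrink a 33-pixel patch by 14 pixels, so their 19 x 19 outputs concatenate;
dropout (default rate 0.3) is applied to the concatenated maps, and a
convolutional output layer with one 19 x 19 kernel per class (four: the
three tissue classes plus background) followed by a channel-wise softmax
produces the class distribution. The pooling sizes are the unique small
arrangement compatible with three local convolutions of those kernel
sizes, stride-1 pooling, and pathway-size equality with the 15x15 global
convolution. The composed receptive field is exactly 33
(`receptive_field()`), verified in the tests by perturbation probing.

**Normalization statistics.** The normalization step is defined by the
formula above; the open design question is *which* population µ and σ²
refer to. Computing them per sample over the current feature map makes the
operation depend on the spatial extent of the input, so a full-image pass
and a patch pass would disagree — breaking the defining contract of dense
inference (below). `octplaque` therefore computes the statistics per
feature map over each training batch and maintains running averages that
are frozen at inference, making the inference-time network exactly
convolutional. The standalone formula is exposed as
`feature_normalize()`.

## Cascade and two-phase training

A single patch classifier sees no label context. The cascade
(`train_cascade()`) fixes this in two stages: stage 1 is trained on
33 x 33 x 3 patches; applied convolutionally to the co-centered 65 x 65
patch it produces a 33 x 33 x 4 probability map, which is concatenated
with the 33 x 33 x 3 RGB patch into a 33 x 33 x 7 input
(`build_cascade_dataset()`) on which stage 2 — the same architecture with
7 input channels — is trained. At inference the stage-1 map is computed
once per image, not per patch.

Training (`train_network()`) uses RMSprop with squared-gradient decay 0.9
and categorical cross-entropy; the loss is not otherwise specified by the
method and cross-entropy is the standard pairing with a softmax
distribution output. Learning rate, batch size and epochs are exposed;
the desk-scale defaults in `pipeline_config()` (1e−3, 64, 6) were chosen
for the phantom demo, while `train_config()` defaults to the more
conservative 1e−4/128/20 appropriate to larger datasets.

Class imbalance is handled twice. First, `balance_by_augmentation()`
raises every class to the majority count using horizontal/vertical flips
of randomly chosen minority patches (each original contributes at most its
two distinct flips before resampling kicks in), so per-label counts are
exactly equal. Second, *two-phase training* (`two_phase_train()`)
retrains only the output layer on a patch sample with the natural class
distribution, re-calibrating the class priors that exact balancing
distorted; every hidden weight and normalization statistic is bit-identical
across phase 2, which the tests verify exactly. Phase 2 runs the hidden
network in inference mode (frozen statistics, no dropout) — that is what
makes the freeze exact rather than approximate.

## Dense inference

Because every layer is a valid convolution or a stride-1 pool,
`predict_dense()` classifies all pixels of an image in one forward pass,
and its output at every pixel equals the patch classifier applied to the
33 x 33 patch centered there — the package's headline equivalence, tested
for random weight draws of both the 3-channel and 7-channel networks at
tolerance 1e−4. Borders are handled by reflecting the depth axis and
wrapping the angular axis (the same padding used at patch extraction, so
the equivalence holds at borders too). `predict_cascade()` runs both
stages densely, labels each pixel by maximum probability (ties toward the
higher class index), forces everything outside the ROI to background, and
`remove_small_regions()` absorbs connected components smaller than
`min_area` (default 64 pixels; 4-connectivity with angular wrap-around,
majority-neighbor reassignment, background on ties).

## The phantom

`phantom_spec()` / `generate_pullback()` emulate the features the method
actually relies on, with analytic ground truth:

* a dark lumen bounded by a smooth closed contour (base radius plus a
  sinusoidal wobble whose phase drifts along the pullback), topped by a
  thin bright interface rim so the axial gradient peaks exactly at the
  true contour — this makes noise-free DP recovery exact, which the
  acceptance tests require;
* plaque regions as annular sectors attached to the lumen: rectangles in
  (depth-beyond-contour, A-line) space, so areas and label maps are exact;
* class-conditional textures following the consensus appearance: fibrous
  bright and uniform; calcified and lipid equally dark (their means are
  intentionally identical) separated only by texture unevenness — a coarse
  blotch field for calcified — and border character, sharp versus a
  four-pixel ramp (`border_sharpness` 1 vs 0.25);
* a guidewire shadow rendered as multiplicative attenuation (factor 0.08)
  over an angular band from the lumen outward, jittered by ±1 A-line per
  frame;
* additive Gaussian sensor noise (default SD 8 on a 0–255 scale), with
  class-mean separations of at least three noise SDs.

The default scale is reduced — 256 depth samples x 128 A-lines x 12
frames — so the full pipeline trains in minutes on one CPU; the full
clinical geometry (976 x 504, 271 frames) is available by argument. What
the phantom does **not** emulate: OCT light transport (no attenuation
coefficients, no speckle statistics beyond the Gaussian/blotch fields
above), mixed or layered plaques, stent struts, or inter-observer label
noise. Passing the phantom benchmark therefore demonstrates that the
pipeline's machinery — geometry, training, cascade conditioning, dense
inference, evaluation — is correct and learnable signal is exploited; it
does not certify clinical-grade accuracy on real pullbacks.

## Evaluation

`confusion()` counts one-vs-rest TP/FP/TN/FN per class inside the
evaluated region; `compute_metrics()` applies precision = TP/(TP+FP),
recall = TP/(TP+FN), F1 = 2pr/(p+r), and macro F1 as the arithmetic mean
of per-class F1 over the three tissue classes (background is excluded from
the macro average by default; a flag includes it). Empty denominators are
defined as zero and flagged; classes absent from an image's truth are
skipped for that image. Metrics are computed per test image and averaged
— `per_image_ci()` reports both a 1.96·SD/√n half-width and the sample SD,
since a published "±" may be either — and pooled over all pixels as a
second view; the two aggregations genuinely differ, which is why a macro
F1 recomputed from *mean* per-class precision/recall can disagree with a
per-image average by a few hundredths. Paired model comparisons use the
Wilcoxon signed-rank test (`wilcoxon_signed_rank()`: zero differences
discarded, exact null for ≤ 15 non-zero pairs, normal approximation with
continuity correction above, degenerate all-zero case flagged).

## Numerical and design choices

* Coordinates: polar rows are depth from the catheter (0-based in all
  public interfaces); angle 0 maps to the Cartesian +x axis, increasing
  counter-clockwise. The network operates on polar rasters; Cartesian
  conversion (`polar_to_cartesian()`, bilinear, 1024 x 1024 default) is
  for display and overlays.
* One fixed monotone colormap (default "sepia") renders grayscale frames
  to the RGB space the network consumes, identically at train and test
  time.
* Patch sizes 65/33 must be odd so the center pixel is well defined;
  patches overrunning the raster edge use reflect (depth) / wrap (angle)
  padding rather than being discarded.
* Training patch extraction uses a stride grid (default 2–4 on the
  phantom) rather than every pixel, with per-class caps, purely to bound
  desk-scale dataset size.
* The validation split is made at the level of whole source frames so no
  image contributes patches to both sides.
* Weight initialization is He-normal; all randomness (weights, shuffling,
  dropout, subsampling, phantom synthesis) flows from explicit seeds, and
  identical seeds reproduce runs bit-exactly.
* Degenerate inputs are contracts, not crashes: an empty ROI yields an
  empty patch set, a uniform pullback still returns a (flagged) guidewire
  path, `min_area = 0` is the identity, a learning rate of 0 performs no
  update.

## Problem sizes used in the shipped runs

The test-suite demo and the acceptance benchmark use the default reduced
phantom (12 frames of 256 x 128), a slim network (8/8/8 local, 16 global
maps), about 350 patches per class after balancing, 6 + 3 training epochs
per stage, and 3 held-out frames; these sizes were chosen as the smallest
at which every stage still exercises its full code path and the held-out
macro F1 comfortably clears 0.85. All of them scale up by configuration.

## Known limitations

* The from-scratch optimizer is plain RMSprop; there is no learning-rate
  schedule, weight decay, or early stopping beyond best-validation-epoch
  selection.
* Dense inference recomputes overlapping pooling windows rather than
  sharing them; it is fast enough at desk scale but not optimal.
* Guidewire detection assumes a single shadow band.
* Predictions are per frame; no smoothing along the pullback is applied.
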