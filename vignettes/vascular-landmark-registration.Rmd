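---
title: "Vascular-landmark registration of fundus images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vascular-landmark registration of fundus images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fundusreg)
```

## The problem and the model

Two fundus photographs of the same retina, taken at different visits or with
different modalities, are related (to good approximation, for the nearly
planar posterior pole) by a 3 × 3 projective homography. `fundusreg`
estimates that homography from *vascular landmarks*: bifurcations and
crossovers of the retinal vessel tree, which are stable under illumination
change, lesion development, and modality switches. The pipeline is

CLAHE → vessel segmentation → junction detection → skeleton calibration →
keypoints/descriptors → matching → robust homography → warp,

with an evaluation layer (confusion metrics, ROC AUC, and the success-rate
curve over control-point error thresholds 0–25 px).

## Preprocessing

CLAHE runs per 8 × 8 tile grid with clip limit 2.0 (the grid is standard for
fundus work; the clip limit is a common default and exposed in
`clahe_params()`). RGB images are equalized on the green channel — the
channel with the strongest vessel contrast — and the result is applied as a
luminance gain. Training augmentation is flips plus rotations about the
image center (bilinear for images, nearest-neighbor for masks so they stay
binary); multiples of 90° are exact index permutations, which is why vessel
pixel counts are preserved exactly there and only to ~5% at arbitrary
angles.

## Vessel segmentation network

`build_vsn()` builds an encoder–decoder network. Downsampling is by stride-2
3 × 3 convolutions, halving the spatial size per level (inputs must be
divisible by `2^levels`); upsampling is by 2 × 2 stride-2 transposed
convolutions with same-level skip concatenation. Two structural modules:

* **multi-input** (`multi_input_fuse()`): the raw image, mean-pooled to each
  level's resolution, passes through a 3 × 3 convolution and is concatenated
  with the level's downsampled features (4 image-branch channels by
  default);
* **connected convolution** (`connected_conv_block()`): two
  conv(3 × 3)–batchnorm–ReLU stages whose second output is concatenated with
  the block input, so each level's output carries both raw and processed
  features.

The head is a 1 × 1 convolution to 2 logits per pixel under softmax cross
entropy, optimized with Adam. Channel widths double per level from `base`.
The full-scale configuration (`vsn_config()`) keeps 100 epochs and learning
rate 5e-6; desk-scale runs in this package use a reduced network (3 levels,
base 8) and learning rate 1e-3, since 5e-6 is calibrated for full-size
training sets and makes no progress in 20 epochs on small phantom sets.

Both networks run on the package's own convolution engine: im2col (C++) plus
BLAS matrix products, with hand-derived backward passes for convolution,
transposed convolution, batch normalization and ReLU. Gradients are verified
against central finite differences in the test suite. Batch normalization
uses per-call batch statistics during training (effective batch is one
image, so statistics are per-image over space) and running averages at
inference.

With no trained model, `segment_vessels()` falls back to a multiscale
Hessian ridge (vesselness) filter with automatic polarity selection (dark
vessels on fundus images, bright on angiograms). The dark rim of the
circular field of view is itself a strong ridge, so the filter suppresses
responses outside an eroded estimate of the field of view — without this the
rim dominates the response normalization.

## Junction detection network

`build_jdn()` follows the one-stage anchor-based design: a residual backbone
(blocks `ReLU(R(x) + I(x))` with R the 1 × 1 → 3 × 3 → 1 × 1 conv sequence
and I a dimension-matching shortcut) producing C1–C5 at strides 2–32; a
feature pyramid where `M_i = conv1x1(C_i) + upsample2(M_{i+1})` (3 × 3
transposed convolution, element-wise addition), `P_i = conv3x3(M_i)`, and
P6/P7 by stride-2 convolutions; and classification/regression subnets shared
across levels. Anchors come in two scales {1, √2} and three aspect ratios
{1, 2, 0.5}; the package pins the area-preserving parameterization
H = BA·S/√AR, W = BA·S·√AR in a regression test (the common alternative
without the radical agrees at AR = 1 but does not preserve area). Each
location carries 6 anchors; decoding applies the regression deltas,
thresholds scores, runs NMS (IoU 0.3), and returns at most 200 boxes —
junction counts on fundus images stay below that cap.

Training: focal loss (γ = 2, α = 0.25, the standard focusing and balance
values) on anchors assigned by IoU (≥ 0.5 positive,
< 0.4 negative, best anchor per ground-truth box forced positive), smooth L1
on positive-anchor box regressions, both normalized by the positive count;
SGD with momentum 0.9 under cosine learning-rate decay, peak 0.01, plus
global gradient-norm clipping at 5 (stabilizes the focal loss on one-image
batches). Ground-truth boxes are squares (default 24 px at reference scale,
16 px on the 128-px desk-scale phantoms) centered on junction points. The
preferred input representation is the binary vessel mask, which carries the
most distinct vessel information.

## Calibration

A junction is a skeleton pixel where three or more branches meet. For each
detected point, `calibrate_junctions()` crops a window (half-size 12 px),
skeletonizes it (Zhang–Suen thinning), prunes spurs (4 endpoint-removal
passes — thinning a wide vessel leaves short side spurs whose roots mimic
junctions), computes the 8-neighborhood crossing number, and snaps the point
to the branch pixel nearest the centroid of the closest ≥ 3-branch cluster
within the snap radius (8 px); points with no qualifying pixel are dropped.
The cluster step matters because a thinned X-crossing yields two adjacent
3-valent pixels straddling the true crossing rather than one 4-valent pixel.
Calibration is idempotent, and every surviving point lies on a ≥ 3-branch
skeleton pixel. `detect_junctions_skeleton()` applies the same machinery to
a whole mask (with stronger pruning, 8 passes) and is the detection route
used when masks are available.

## Registration

Keypoints are placed at calibrated junctions (plus up to 4 auxiliary
gradient maxima within 5 px, configurable). Orientation assignment uses a
36-bin Gaussian-weighted gradient-orientation histogram with parabolic peak
interpolation; **every peak within 60% of the maximum yields a keypoint**.
This differs from single-peak assignment deliberately: a junction
neighborhood has 3–4 near-equal vessel-arm peaks, and which one wins is
noise-driven (single-peak orientation repeatability across views measured
~17% on phantoms; multi-peak ~80%). Descriptors are the standard 128-value
SIFT layout — 4 × 4 spatial cells × 8 orientation bins, sampled on a patch
rotated to the keypoint orientation, trilinearly soft-binned, Gaussian
weighted, normalized, clipped at 0.2, renormalized — computed on the CLAHE
image with gradients smoothed at σ = 2 and a 40-px support (spacing 2.5 px),
sized so the descriptor sees neighboring vessel structure, not just the
junction's own arms.

Matching is Euclidean nearest-neighbor with the 0.84 ratio test and a
one-to-one filter (lowest distance wins per sensed keypoint); a mutual-check
variant is available by flag. `estimate_homography()` is classical RANSAC:
minimal 4-point normalized-DLT solves, inlier counting at the reprojection
threshold (3 px), adaptive iteration count, and an iterated refit on the
final inlier set.

`register_pair()` uses a landmark-aligned model search instead of raw
descriptor-inlier counting. At desk scale an image carries only ~12
junctions; descriptor matches are few and only ~50–60% correct, and a
4-point hypothesis needs all four correct. Since the realistic
inter-visit transform is near-similarity (rotation ≤ 20°, scale 0.9–1.1,
perspective ~1e-4), hypotheses are generated from *pairs* of matches
(closed-form similarity; pairs enumerated exhaustively, with a minimum
15-px separation guard) and scored by how many calibrated junctions they
bring into one-to-one alignment within 5 px — the landmarks carry the
reliable geometry, the descriptors only propose. If no pair hypothesis
aligns enough junctions, single-match hypotheses (anchor position, rotation
from the keypoint-orientation difference, scale on a 0.8–1.25 grid) cover
the case where all true matches sit on one junction. The best hypothesis is
then refined ICP-style: junctions re-matched under the current model and the
model refit — a least-squares similarity below 8 pairs, a full projective
normalized DLT once at least 8 well-spread pairs align. The final matrix is
normalized to `h[3,3] = 1` and the sensed image is warped by inverse-mapped
bilinear resampling.

For multimodal pairs (fluorescein angiography), vessel contrast inverts and
every image gradient flips sign, so descriptors no longer transfer. When the
first attempt aligns few junctions, `register_pair()` retries against the
intensity-inverted sensed image and keeps whichever attempt aligns more
junctions.

## Synthetic data: what it emulates, and what it does not

`generate_vascular_tree()` grows recursive binary trees inward from root
stubs on the circular field-of-view boundary: segment lengths ~0.2 of the
image side with 0.85 per-generation taper and mild curvature, branching with
probability 0.85 per node at half-angles 20–45°, widths starting at 5 px
(256-px image) decaying by 0.82 per generation, up to 6 generations from 3
roots — roughly the vessel calibers and junction density of standard fundus
photographs scaled to 256 px. Crossovers arise when branches properly
intersect; growth *rejects* tangent near-misses and crossings shallower than
35° or closer than 12 px to another junction, so that every junction visible
in the mask is recorded — the ground truth is exhaustive by construction,
which the detection F1 tests require. Junction coordinates are anchored to
the rendered mask's skeleton (centroid of the nearby ≥ 3-branch cluster):
the analytic branching corner sits up to (w/2)/sin(half-angle) away from the
point where the two daughter lumens visibly separate, and the skeleton
point is what an annotator would mark.

Rendering places dark vessels (≈ 60 gray levels of contrast) on a bright
background with a radial illumination gradient, smooth texture, additive
Gaussian noise (σ = 3), and zero outside the field of view; angiography
style inverts the polarity. `generate_pair()` composes the true homography
as center rotation/scale, translation, and third-row perspective terms,
resamples the reference mask through its inverse to make the sensed mask,
renders both with independent noise, and optionally defocuses (Gaussian
σ = 2) or inverts the sensed image.

What the phantoms do **not** emulate: pathology (exudates, hemorrhages,
drusen), the optic disc and macula, vessel caliber pulsation, real camera
vignetting and chromatic structure, and the rich choroidal texture that
makes real SIFT descriptors more distinctive. Passing the synthetic suites
therefore demonstrates the pipeline's geometric and algorithmic correctness
and its robustness to the modeled degradations — not clinical-grade accuracy
on real databases, which requires full-scale training and evaluation on
fundus image collections.

## Numerical choices and degenerate inputs

* Coordinates are 1-based with pixel centers at integers, x = column,
  y = row; point and correspondence files default to 0-based on disk
  (`origin` argument).
* The homography constructor requires `|h33| > 0` and a nonzero determinant;
  `transform_point()` raises on points whose denominator vanishes
  (projective horizon).
* RANSAC degeneracy: minimal samples with any collinear triple are skipped;
  a final inlier set is degenerate if it has fewer than 4 distinct points or
  rank-deficient spread (smallest covariance eigenvalue test). Ties in NMS
  and matching are broken by score/distance order, deterministically.
* All stochastic stages (weight init, training order, augmentation, RANSAC
  sampling) are seeded; identical seeds give bit-identical results. Seeds
  are handled with `withr::with_seed`, so library calls never disturb the
  caller's RNG state.
* Constant-intensity images pass through CLAHE unchanged (no contrast to
  redistribute); flat descriptor patches are flagged invalid and their
  keypoints dropped.

## Desk-scale experiment sizes

The test suite trains the reduced segmentation network (3 levels, base 8) on
200 held-out-disjoint 64 × 64 phantom patches for 20 epochs (held-out Dice
threshold 0.75), overfits the toy detector on 10 phantom masks for 300
steps (recall threshold 0.8 at 5 px), and runs 50 registration pairs
(rotation ≤ 20°, translation ≤ 30 px, |perspective| ≤ 1e-4) plus 20
degraded-quality pairs. `scripts/acceptance.R` repeats the same experiments
with the segmentation run at 120 patches × 12 epochs, a size chosen so the
whole script reruns in about ten minutes on one CPU while leaving the
conclusions unchanged.

## Known limitations

* Descriptors are single-scale (junctions are detected at image scale); a
  scale-space pyramid is out of scope.
* The similarity-first model search assumes the transform envelope above;
  pairs far outside it (e.g. 45° rotation *and* strong shear) would need the
  pure 4-point path in `estimate_homography()`.
* The conv engine is CPU-only and single-image; it is sized for desk-scale
  training, not full-database runs.
* Bifurcation vs crossover is recorded in the generator's ground truth but
  not distinguished by the detector or used downstream.
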