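---
title: "NeuroTexNet: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{NeuroTexNet: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

NeuroTexNet implements a staged pipeline for multiclass brain-tumor
classification on 2-D grayscale slices: preprocessing, augmentation,
edge-based segmentation, second-order texture features, metaheuristic
feature selection, and a residual softmax classifier.  This vignette
explains each model, the tunable parameters that matter, the synthetic
world the tests run in, and the numerical decisions made where the design
was genuinely open.

## The synthetic phantom world

External MRI corpora are replaced by a seeded phantom generator
(`phantomSpec()`, `generatePhantom()`, `generateImageDataset()`).  A
phantom is exactly what the pipeline's operators consume, no more:

* a bright elliptical **skull ring** (intensity 230) separated by a 2-px
  gap from the brain, so skull stripping has something to strip;
* a mid-intensity **brain ellipse** (120) on a dark background (15);
* one **tumor disk** whose interior carries a class-specific texture, so
  edge detection has a closed boundary to find and the texture features
  are discriminative.

The three tumor classes (standing in for meningioma / glioma / pituitary)
are sinusoidal gratings with periods 2, 4 and 8 px and amplitudes 60, 45
and 50 around a base intensity of 140.  Two numerical details matter:

* the grating is a **cosine on the integer pixel grid** (a π/2 phase
  shift).  A sine of period 2 evaluated at integer — or, for even image
  sizes, half-integer centered — coordinates samples exactly its zeros and
  the texture vanishes;
* the amplitudes were fixed once so that the distance-1 co-occurrence
  contrast differs pairwise between classes by at least a factor 2
  (measured ratios ≈ 6.5, 3.3 and 21 at 8 gray levels), the separability
  the feature extractor relies on.  This is the only calibrated constant
  in the generator and it is asserted by a test against a brute-force
  oracle.

Default noise is 1% salt-and-pepper plus Gaussian σ = 5 — enough to
exercise the optional denoiser without drowning the texture.  Everything
is derived from one master seed; identical spec + seed is bit-identical.
The phantoms deliberately do **not** model MRI physics (bias fields,
partial volume, k-space artifacts); a green test establishes that the
pipeline's operators work as specified, not that they would reach any
particular accuracy on clinical data.

`generateFeatureTable()` plants a separate, simpler world for the
selection stage: informative columns are class-conditional Gaussians with
unit SD whose class means are **evenly spaced over a total spread of
`effect_size` SD units**, assigned by a fresh random permutation per
column; noise columns are standard normal.  The total-spread reading was
chosen over adjacent-class spread because it makes each informative column
non-redundant under the wrapper objective below (at effect 3 a
nearest-centroid classifier on the five informative columns alone sits
near 95% training accuracy, with adjacent centroids √5 · 1.5 SD apart);
with adjacent-class spreads of 3 SD, three columns already separate the
classes perfectly and the subset-size penalty would *correctly* discard
the rest, making "recovery of the informative set" an ill-posed target.

## Preprocessing

* **Median filter** (`medianFilter()`): square window, default 3×3, edge
  replication.  Idempotent on constants, never widens the intensity
  range.  Denoising is optional; the `"auto"` rule applies it when the
  estimated fraction of extreme-valued isolated pixels exceeds 0.5%.
* **Skull stripping** (`stripSkull()`): Otsu binarization → erosion with a
  disk of radius `max(3, image_size/32)` → keep the largest connected
  component → dilation with the same disk, intersected with the original
  foreground.  The erosion disconnects the thin bright ring from the
  brain; the published description of this step is terse, so the sequence
  here is a standard reconstruction and is flagged as such.
* **Augmentation** (`augmentImage()`): clockwise rotation about the center
  pixel by the plan's angles (default ±15°, ±90°) with bilinear
  interpolation (nearest available for exact tests), each optionally
  flipped; out-of-frame pixels are 0.  Output count is exactly
  |angles| · (|flips| + 1).

## Adaptive Canny with Mayfly adjustment

`detectEdges()` runs: LoG prefilter → weighted smoothing → Sobel-form
gradients → optional swarm adjustment → non-maximum suppression →
hysteresis.

* **LoG image-of-interest**: the response at scale `log_sigma` (default 1)
  is computed with a zero-sum discrete kernel; pixels whose intensity is at
  least the response are retained, the rest zeroed.  The underlying
  description ("the image is split in half using the LoG value") is
  ambiguous; this retention reading is a documented reconstruction.
* **Smoothing kernel**: 3×3 of ones with center weight β (default 2),
  normalized by 8 + β so constants are preserved.
* **Gradients**: the standard ±1/±2 kernel pair; magnitude uses the square
  root (the printed squared form is available behind `squared = TRUE` for
  auditability); direction α = arctan(|Px|/|Py|), 90° when |Py| = 0 (the
  printed "tan" of a ratio is not an angle, so the arc is restored).
* **Non-maximum suppression** is *sub-pixel*: each pixel is compared
  against the magnitude linearly interpolated at unit distance along its
  exact gradient direction on both sides.  Four-direction quantized NMS
  was tried first and rejected for a concrete reason: on a square phantom
  it leaves exact plateau ties on the corner diagonals (two pixels with
  identical magnitude each "not smaller" than the other), producing edge
  pixels 2.2 px off the true boundary.  Interpolation breaks those ties
  and is what modern Canny implementations do.
* **Hysteresis**: thresholds are fractions of the maximum gradient
  magnitude (defaults 0.1 / 0.2); weak components are kept only when they
  contain a strong pixel (8-connected).  Magnitudes below 10⁻⁶ are treated
  as zero so constant images give empty maps despite floating-point noise.
* **Mayfly adjustment** (`mayflyOptimize()`): a small swarm over the
  distance-coefficient plane (d₁, d₂), bounded by default to
  [0, 0.25 · max |P|] — perturbations beyond the gradient scale destroy
  the field.  Each candidate draws fresh a₁, a₂ ∈ [−1, 1], shifts the
  gradient arrays globally (the update carries no pixel index, so the
  scalar reading keeps the search two-dimensional and reproducible),
  re-derives the direction, and is scored by the default reference-free
  fitness: fraction of edge pixels with ≥ 2 edge neighbors plus mean
  normalized gradient magnitude over edge pixels (range [0, 2]) — strong,
  unfragmented contours score high.  Global-best elitism makes the
  best-so-far trace non-decreasing; a Pratt figure-of-merit fitness is
  available when a truth boundary exists.
* **ROI segmentation** (`segmentRoi()`): morphological closing (disk
  radius 1), hole filling by border flood-fill, largest filled component.
  An edge map that encloses nothing yields the *empty-ROI signal* (an
  all-FALSE mask with a message), not an error; the pipeline then falls
  back to the brain mask.

## SGLDM texture features

`quantizeImage()` maps intensity to `floor(p · Xg / (range_max + 1))`
levels (default Xg = 32, balancing sparsity against discrimination on
8-bit input).  `cooccurrence()` counts gray-level pairs at displacement
(v, μ), μ ∈ {0, 45, 90, 135}, v ∈ {1, 2} by default, both pixels inside
the ROI; symmetric counting (on by default, standard GLCM practice) adds
reversed pairs.  Probabilities are counts over their total.  Eight
Haralick-family features are computed per matrix — energy, contrast,
entropy (natural log, 0·log 0 = 0), homogeneity, correlation (defined as 1
at zero marginal variance, with a message), variance, maximum probability,
dissimilarity — and concatenated per (v, μ) in a stable documented order
rather than averaged over angles, preserving the directional structure for
the selector to prune.  Every formula is cross-checked in the tests
against an independent double-loop oracle.

## Enhanced chimp optimization and wrapper selection

The continuous optimizer (`choaOptimize()`) ships **both readings** of the
enhanced update, because the printed equations are internally
inconsistent (the final position update drops the prey-distance term that
the base equations define):

* `"as_printed"` (default): position ← prey − 2 f cos(r₂)(2 sin(r₁) − 1);
  the prey-distance Dr is still computed for diagnostics.  This is a
  shrinking random search around the best-so-far point.
* `"standard"`: position ← prey − a₃·Dr with Dr = |a₁·prey − a₂·position|
  and the sine/cosine coefficients a₃ = 2 f sin(r₁) − f, a₁ = 2 cos(r₂);
  the conventional chimp form, used wherever convergence matters.  A
  `coef_form = "linear"` switch recovers the unenhanced coefficients
  (2 f r₁ − f, 2 r₂) for regression against the published update.

The control coefficient decays as f(t) = 2.5 · (1 − t/T)² — "nonlinear,
from 2.5 to 0" fixed as a quadratic ease-out with exact endpoints; the
form is pluggable.  r₁, r₂, a₂ are drawn per dimension per update.  The
four chimp roles share one update rule; role-specific dynamics are out of
scope.  Non-finite fitness candidates are rejected and counted.

`selectFeatures()` wraps the optimizer: positions in [0,1]^D threshold at
0.5 into masks (an empty mask is repaired to the single highest-position
feature), and the objective is
ω · (stratified 5-fold CV error of 5-NN on the included, standardized
features) + (1 − ω) · |mask|/D with ω = 0.99.  Fold assignment is drawn
once per call, so the objective is deterministic across evaluations.  For
large (augmented) training sets the wrapper fitness uses a seeded
stratified subsample capped at `max_n = 300` rows — a cost cap on the
O(n²) k-NN inside ~600 fitness evaluations, not a statement about the
data.

## Residual network

`networkConfig()` describes the canonical 152-layer bottleneck layout:
stem 7×7 stride 2 → 3×3 max-pool → stages [64,64,256]×3, [128,128,512]×8,
[256,256,1024]×36, [512,512,2048]×3 (the printed "521x" width is read as
the obvious 512 typo) → global average pooling → dropout → softmax head
whose width is `class_count` (the legacy 1000-way head serves no purpose
here).  `describeNetwork()` reports block counts and spatial sizes (56,
28, 14, 7 for a 224 input) from the configuration alone;
`depth_scale` ceilings the block counts for desk-scale runs (0.05 gives
1, 1, 2, 1).  Stage transitions use stride-2 1×1 projection shortcuts;
blocks are pre-activation, so a block with zeroed branch weights is an
*exact* identity — an invariant the tests assert.  Feature mode stacks
residual fully-connected blocks of the same transform-plus-shortcut form
over the selected-feature vector; it is the default dataflow because the
pipeline's stated input to classification is the selected features, while
image mode reproduces the tabulated convolutional architecture.  Batch
normalization is deliberately omitted: the reference table does not
mention it and the desk-scale networks train without it.

Training (`trainNetwork()`) is plain SGD with momentum 0.9, learning rate
10⁻³, batch 16, 50 epochs — none of these are stated anywhere, all are
configurable and recorded.  The loss is the negated indicator
log-likelihood (one-vs-rest expansion for m classes, probabilities clipped
at 10⁻¹²) averaged over all indicator entries, so it is nonnegative, 0 at
perfect prediction, and exactly ln 2 when every probability is 0.5.
"Adaptive dropout" is read as rate-0.5 dropout whose rate halves when the
monitored loss plateaus for 3 epochs (fixed-rate mode available);
dropout sites are distributed evenly through the image-mode stack (10 by
default).  Gradients are implemented by hand (im2col convolutions,
rowsum scatter-adds) and verified against central finite differences in
the tests.  All layer arithmetic is ordinary BLAS; there is no GPU path,
and training the unscaled 152-layer network is explicitly out of scope.

## Metrics

Confusion matrices put predicted classes on rows and actual classes on
columns.  Accuracy, precision and recall follow the standard one-vs-rest
count formulas exactly; zero denominators yield a defined 0 with a
warning.  Because the source of the headline accuracy is ambiguous about
micro versus macro averaging, both are reported and labeled.  ROC curves
are one-vs-rest, thresholded over all distinct scores, with trapezoidal
area; constant scores give exactly 0.5 and perfect separation exactly 1.

## Pipeline orchestration

`runPipeline()` fixes the stage order: simulate → stratified 80/20 split →
denoise (optional) → skull strip → augment *training split only* →
edge-detect and segment → features → selection → training →
evaluation.  The split precedes augmentation so no augmented copy of a
test image can leak into training.  One pipeline-specific choice: after
skull stripping, edges within 2 px of the brain-mask boundary are removed
before ROI filling — they are artifacts of the masking step, not image
structure, and would otherwise make the brain outline the largest
enclosed region.  Every stage seed derives deterministically from the
master seed, and `runReportJson()` serializes the report so that repeated
runs are byte-identical.  The Mayfly stage is off by default in the
pipeline (a per-image swarm search multiplies cost ~100-fold); it remains
a first-class option.

## Known limitations

* Phantoms are geometric, not anatomical; texture is stationary inside the
  tumor disk.  Results do not transfer to clinical MRI.
* The as-printed chimp update ignores the current position entirely; it is
  retained for fidelity, not recommended for optimization work.
* ROI segmentation assumes one dominant enclosed region; overlapping or
  open structures fall back to the brain mask in the pipeline.
* Image-mode training at full width/depth is computationally out of reach
  in plain R; the architecture is exercised at reduced depth and verified
  structurally.
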