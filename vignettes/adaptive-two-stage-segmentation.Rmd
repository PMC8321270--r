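---
title: "Adaptive two-stage segmentation of small lesions: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive two-stage segmentation of small lesions: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptseg)
```

## The problem

Small, sparse targets — lung nodules in chest CT, brain metastases in T1
MRI — occupy a vanishing fraction of the volumes they sit in: typical
foreground fractions are $10^{-2}$ to $10^{-3}$, and the individual objects
are distinct and roughly compact. A dense 3D convolutional segmentation
network spends essentially all of its arithmetic on background, which is
why such models need minutes per scan on a CPU. adaptseg implements a
coarse-to-fine alternative built around that sparsity.

## The model

**Stage 1 — localization.** The input volume (intensities already scaled to
$[0,1]$) is average-pooled once, $2\times$ per axis. A small
fully-convolutional path — a stem convolution at the $\times 2$ scale, two
stride-2 convolutions to the $\times 4$ and $\times 8$ scales, residual
blocks at the coarsest scale, and a $1^3$ convolution with a sigmoid —
produces one foreground probability per $8^3$ voxel block. Its training
target is the ground-truth mask max-pooled with an $8^3$ kernel: a coarse
cell is positive iff its block contains any foreground voxel. Every
convolution is $3^3$, zero-padded, followed by batch normalization and ReLU
(except the output head). Features at the $\times 2$, $\times 4$ and
$\times 8$ scales are retained as a pyramid.

**Region proposal.** The coarse map is binarized at the fixed threshold 0.5
(comparison `>=`; no threshold tuning anywhere in the pipeline), split into
connected components (26-neighbourhood by default), and each component is
wrapped in its tight bounding box expanded by a margin of one coarse cell —
8 voxels at full resolution — to absorb boundary errors of the coarse
stage. Larger margins increase the processed volume linearly, so the
minimum useful margin is the default.

**Stage 2 — detailed segmentation.** For each proposed box the decoder
consumes the cropped $\times 8$ features (a convolutional trunk with
residual blocks), upsamples by nearest-neighbour $\times 2$ steps, joining
the cropped $\times 4$ and $\times 2$ pyramid features by concatenation as
in a U-Net decoder, and finally joins the raw image crop at original
resolution before a $1^3$ sigmoid head. Each box is predicted
independently, and the outputs are written into a prediction map initially
filled with zeros; voxels outside every box are exactly 0 by construction.
The fraction of the volume inside the box union is reported as
`fraction_processed` — on sparse data it is a few percent, which is where
the CPU speed-up comes from.

## Architecture defaults

The channel plan is configurable ([net_config()]). Defaults were chosen as
a CPU-efficiency decision: fine scales are cheap in parameters but dominate
arithmetic, coarse scales are the reverse. With `base_width` $w$ (default
16), the stage-1 scales carry $(w/2,\; w,\; 2w)$ channels at
$(\times 2, \times 4, \times 8)$, with residual blocks only in the coarse
trunk, keeping the localization path deliberately light. The stage-2
decoder carries $(2w,\, w,\, w/2,\, w/4)$ channels at the
$(\times 8, \times 4, \times 2, \times 1)$ steps, with its residual blocks
at $\times 8$; most of its parameters therefore sit where compute is
cheapest, and under every supported width the detailed stage has more
parameters than the localization stage while inference stays fast. The raw
image crop enters the decoder at full resolution (`use_image_skip`,
default on): without it the decoder could not resolve detail beyond the
$\times 2$ grid it inherits from stage 1. All three retained pyramid scales
feed the decoder.

Upsampling is nearest-neighbour followed by convolution (avoids
checkerboard artifacts of transposed convolutions); encoder downsampling is
by strided convolution; the input downsampling operator is average pooling
(analytically testable, no aliasing surprises). A ResBlock is
conv–BN–ReLU–conv–BN plus the identity, ReLU after the addition; channel
counts within a trunk are constant so no projection shortcut is needed.

## Training protocol

Training is two-phase on the same training set (enforced softly by a
manifest hash recorded in both checkpoints):

1. **Stage 1** minimises weighted cross-entropy between the coarse
   probability map and the max-pooled ground truth. The positive-class
   weight defaults to the negative/positive coarse-cell ratio of the
   training set, clamped to $[1, 100]$ — coarse targets are extremely
   imbalanced and an unweighted loss collapses to the background class.
2. **Stage 2** is trained with the stage-1 weights frozen (bit-identical
   before and after, asserted in the tests). For every training patch the
   frozen stage proposes boxes exactly as at inference; the decoder
   predicts each box, the patch prediction is assembled (zeros outside
   boxes), and soft Dice loss
   $1 - (2\sum pt + \varepsilon)/(\sum p + \sum t + \varepsilon)$,
   $\varepsilon = 1$, is minimised against the patch ground truth. If the
   frozen stage proposes nothing on a patch that does contain foreground,
   the boxes derived from the max-pooled ground truth are substituted so
   the decoder still receives gradient — a cold-start fallback that decays
   to irrelevance as stage 1 converges.

Both phases use SGD with Nesterov momentum 0.9, learning rate $10^{-2}$
reduced to $10^{-3}$ at epoch 80 (of 100 epochs of 100 iterations), batch
size 32, patches of $64^3$ voxels, and object-aware patch sampling: with
probability 0.5 a patch is constrained to contain at least one foreground
voxel, drawn uniformly over all such origins (enumerated with a summed-area
table), otherwise uniformly over all origins. Batches draw cases uniformly
with replacement. Soft ground truth (e.g. mean annotation masks) enters the
Dice loss directly and is binarized at 0.5 wherever connected components or
max-pooled targets are needed — reusing the pipeline's single fixed
threshold. Batch-norm running statistics use momentum 0.1 with biased
variance; batch statistics are shared across all boxes of a stage-2 batch
regardless of their sizes.

## Inference

Stage 1 runs over arbitrary volume sizes through halo-based tiling
([grid_predict()]): the coarse grid is split into core tiles sized from a
memory budget (default 16 GiB, a standard workstation bound), each tile is
forwarded with a context halo of the stage-1 receptive field, and the halo
is trimmed. Because convolutions are zero-padded and the halo covers the
receptive field, the tiled result equals a single full-volume pass up to
floating-point reordering (asserted at $10^{-5}$). Volumes are padded to a
multiple of 8 by edge replication so the three pyramid scales align
exactly; the output is cropped back.

Overlapping boxes are *not* merged — each component is predicted
independently. Overlapping insertions resolve by write order
(last-writer-wins, default) or voxel-wise maximum (`overlap = "max"`);
inside the overlap the two predictions agree except within the decoder's
receptive-field margin of a box border, so the policy rarely matters. A
volume where no cell reaches threshold yields a valid all-zero prediction
with an empty component list.

## Evaluation

Voxel-global Dice lets large lesions dominate, so quality is measured
object-wise. `object_dice()` computes, per ground-truth object, the Dice
overlap between the object and the predicted mask restricted to the
object's bounding box dilated by 8 voxels, and averages over objects
(missed objects score 0). The localization rule — which predicted voxels
"belong" to an object — is not standardised; the dilated-box context region
is this package's choice, and false positives elsewhere deliberately do not
depress the score because they are priced by FROC instead.

`froc_curve()` sweeps the detection-score threshold over all distinct
scores of the predicted components (scored by maximum predicted
probability; `mean` available). A ground-truth object is hit when a
predicted component overlaps it by at least one voxel — a
segmentation-based surrogate for the centre-in-nodule rule of the public
lung-nodule challenge, which requires nodule-radius metadata this method
does not produce; a minimum overlap fraction is configurable. Average
recall integrates the FROC step function over allowed false-positive rates
0 to 5 per image in steps of 0.01 (501 points); the seven-point variant
(1/8 … 8 FPs per scan) is also provided. The step function is evaluated as
the best recall among operating points with an FP rate at most the allowed
rate, and 0 before the first point.

## The synthetic phantom generator

No public imaging data ships with the package; all experiments run on
phantoms that emulate the statistical structure the method targets: large
volumes, a small Poisson-distributed number of small, distinct,
approximately spherical high-contrast lesions, foreground fraction in the
$10^{-4}$–$10^{-2}$ range. Diameters are lognormal in millimetres (defaults
give an 8 mm median; `phantom_preset("lung_like")` and `"brain_like"`
centre the medians at the clinically used 10 mm and 5 mm small-lesion
thresholds with matching anisotropic spacings). Geometry is computed in
millimetres, so anisotropic voxels are honoured. Lesion placement rejects
overlaps with a two-voxel gap, guaranteeing that mask components and
lesions correspond one-to-one — object-wise metrics then have unambiguous
ground truth. The background is a Gaussian-smoothed noise field centred at
intensity 0.35 with amplitude `noise_sd` (default 0.05) and 4 mm
correlation length; each lesion adds a uniform contrast drawn from
`contrast_range` inside its sphere, with a 0.5 mm Gaussian intensity edge;
the volume is clipped to $[0,1]$. Masks are always hard spheres, which
makes analytic volume checks possible.

What the phantoms do *not* emulate: irregular lesion shapes, anatomy
(vessels, airways, cortex), intensity inhomogeneity, imaging physics, and
annotation disagreement. Passing the end-to-end tests therefore
demonstrates that the implementation learns and localises under the
intended sparsity regime — not that it reaches any particular quality on
clinical data.

## Numerical choices and degenerate inputs

* Threshold comparisons are `>=` at exactly 0.5, fixed and documented.
* Dice smoothing $\varepsilon = 1$: empty-prediction/empty-target patches
  score loss 0 rather than NaN.
* Cross-entropy probabilities are clamped to $[10^{-7}, 1-10^{-7}]$.
* The stage-2 head bias is initialised to $-4$ (a sparse-foreground
  prior). With a zero initialisation the untrained decoder fills each box
  with $p \approx 0.5$, the Dice denominator $\sum p$ is enormous, and the
  per-voxel gradients ($\propto 1/\sum p$) are too small for the reduced
  training schedules to escape — the loss plateaus. Starting from a low
  prior keeps early gradients concentrated on the foreground; this is the
  standard initialisation for heavily imbalanced segmentation heads.
* Connected-component labelling is deterministic (first-encounter order in
  array scan order); box lists are ordered by component label.
* Shapes not divisible by 8 are padded: edge replication for images (no
  spurious gradients), zeros for masks and max-pool targets.
* Volumes smaller than a patch are padded the same way; lesion-free
  volumes train (random patches) and predict (possibly zero boxes) without
  error.
* Training aborts with a diagnostic on a non-finite loss rather than
  continuing silently.

## Problem sizes used by tests and the acceptance script

Training at the reference protocol's full scale (100×100 iterations, batch
32) is a multi-hour CPU run and is not exercised by the automated checks.
The package's own reproduction scale, used both in the test suite and in
`scripts/acceptance.R`, is: 30 training and 10 test phantoms of $96^3$
voxels with 1–3 high-contrast lesions each, `base_width = 8`, and 10 epochs
of 50 iterations per stage with the learning-rate drop moved to epoch 8
(the same 80% point as the reference schedule). On this scale the full
pipeline trains in minutes on one CPU core and reliably reaches high
object-wise recall with a small processed fraction; unit and property tests
use still smaller widths and volumes.

## Known limitations

* Single-channel sigmoid output only; the multiclass softmax extension is
  out of scope.
* Objects larger than a training patch would defeat the box-wise Dice
  signal; the method is aimed at small targets.
* The engine is a purpose-built dense double-precision CPU implementation;
  it has no GPU path, mixed precision, or data augmentation.
* FROC confidence scores come from component-wise maxima of the sigmoid
  output; a model trained to saturation yields few distinct scores and
  hence a coarse curve — adequate for recall-at-FP operating points, not
  for calibration studies.
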