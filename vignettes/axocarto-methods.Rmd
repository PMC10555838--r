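---
title: "Methods: automated axon annotation, multi-constraint registration and region quantification"
author: "axocarto"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated axon annotation, multi-constraint registration and region quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

axocarto re-implements, as an ordinary R package exercised entirely on
synthetic phantoms, the algorithmic core of a whole-brain axon-profiling
workflow for cleared mouse brains imaged by light-sheet fluorescence
microscopy (LSFM): automated voxel-level axon annotation of small 3D cubes,
volumetric training-pool augmentation, centerline-aware evaluation metrics,
the full family of segmentation / style-transfer / multiview / registration
loss functions as pure numeric functions, desk-scale multi-constraint
multiscale 3D registration, and region-wise axon density quantification.
This vignette is the package's own account of the models it implements, the
parameters that matter, the numerical choices made, and what the synthetic
experiments do and do not demonstrate.

## Conventions

All volumes are R arrays with `dim = (depth, height, width) = (z, y, x)`;
the first index varies fastest.  Voxel coordinates are 0-based `(z, y, x)`
triples with voxel centers at integer positions, and all index ranges are
half-open `[low, low + extent)`.  This matches slice-stack storage: a
directory of per-slice TIFFs assembles with the slice index first.  Spacing
is per-axis voxel size in micrometers.

## Cubes, tiling and stitching

The unit of annotation and augmentation is the cube (default 150 voxels per
axis) extracted around a user-chosen center and clamped at volume faces with
zero padding.  Whole brains are tiled into full-sized cubes: tiles advance
by a stride, and the last tile on each axis is shifted inward rather than
padded, so that every tile has the full extent and every voxel is covered at
least once.  Stitching recombines per-cube predictions; overlapping voxels
combine by `max` by default, since binary or probability axon maps should
not be diluted by empty overlap (a `mean` blend is available for intensity
data).  With stride equal to the cube extent, tile-then-stitch is exactly
the identity, which the tests assert voxel-for-voxel.

TIFF volumes are read and written through the `tiff` package: integer data
in [0, 65535] round-trip exactly as 16-bit samples without rescaling, and
float data in [0, 1] (probability maps) are stored as 32-bit samples with
quantization at the 2^-32 level.  General float volumes use NRRD (raw
little-endian encoding, header spacing), which round-trips bit-exactly.

## Synthetic data: what the generators emulate

No external dataset is required; every experiment in the test suite runs on
synthetic inputs with exact ground truth.

**Axon cubes** are branching random-walk centerline trees rasterized as
tubes: a voxel belongs to the ground-truth annotation iff its distance to
the centerline is at most the tube radius, and the intensity falls off as a
Gaussian of the same scale (`peak * exp(-d^2 / (2 * radius^2))`), mimicking
the point-spread blur of light-sheet optics.  A constant background and
additive Gaussian noise complete the cube; the default peak-to-noise ratio
(`snr = 10`) represents a well-stained axon channel.  The exact centerline
raster, thinned to single-voxel width, is stored as the ground-truth
skeleton.  **Artifact cubes** carry only non-axonal structure — a thick
bright vessel (radius several times the axon radius), Gaussian bright
spots, or a bright planar band near a face — and their ground-truth
annotation is all-zero by definition.

**Phantom brains** are smooth ellipsoids containing disjoint ellipsoidal
regions with distinct mean intensities, labeled with ids from a default
region table holding the six major mouse brain regions used as registration
constraints (CTX, CP, HPF, BS, CB, and CBX nested under CB) plus five small
structures (act, fr, mtt, Hb, IPN).  Landmarks sit at region centers.  The
default phantom shape (80 x 114 x 132) equals the coarsest level of the
registration pyramid for the full-size reference grid (320 x 456 x 528), so
registration experiments run at desk scale.  `deformPhantom()` warps a
phantom by a known affine map or deformation field — intensity trilinearly,
labels by nearest neighbor, landmarks exactly through the point map — and
adds fresh noise, producing source/reference pairs with known ground truth.

What the phantoms deliberately do **not** model: stripe artifacts, tissue
damage, autofluorescence texture, intensity inhomogeneity across batches,
and anatomical detail beyond nested ellipsoids.  Passing recovery tests
therefore demonstrate the correctness and identifiability of the objective
and optimizer under controlled conditions, not field performance on real
LSFM brains.

All generator randomness flows from one explicit integer seed through a
local RNG scope; no global random state is touched.

## Automated axon annotation

The annotation pipeline is: Gaussian pre-smoothing (3 x 3 x 3 kernel by
default) -> difference of Gaussians -> thresholding -> fragment connection
by dilation -> 3D skeletonization -> unified-thickness dilation.

* The DoG sigmas default to (1.0, 2.5) voxels, band-passing structures one
  to three voxels wide — the apparent width of axons at the imaging scale
  this workflow targets.  Thick vessels and flat backgrounds fall outside
  the band and are suppressed, which the tests verify comparatively.
* The automatic threshold is Otsu's method computed on the DoG response of
  the cube's nonzero voxels.  A constant cube yields an empty mask with a
  warning rather than an error.
* Fragment connection is morphological dilation by a Euclidean ball
  (radius 1 by default), bridging small gaps so the tree topology survives
  skeletonization.
* Skeletonization is sequential six-subiteration 3D thinning that deletes
  simple points (Bertrand–Malandain local characterization) while keeping
  curve endpoints; it preserves topology, is idempotent on thin curves, and
  is implemented in C++.  Because the six face directions are processed in
  a fixed order, the skeleton of a *thick* mask can shift by a few voxels
  under an axis permutation of the input; centerline metrics inherit this
  (volumetric Dice does not), and the exact-invariance tests therefore use
  already-thin curves.
* Unified thickness: every skeleton voxel extends one voxel along each of
  the six axis directions (7-voxel cross in the interior, clipped at
  faces).

In sparse mode (default) the annotation is the thickened skeleton; in dense
mode it is the binarized-and-connected mask, because the skeleton of an
extremely dense cube no longer reflects the real structure.  The mode is an
explicit flag; no density cutoff is imposed.  Thresholding and connection
are monotone in the threshold (lower threshold, never fewer voxels); the
skeletonization stage is not, so the monotonicity property is asserted on
the binarized-and-connected mask.

On synthetic cubes the full pipeline reaches ClDice >= 0.7 against the
exact ground truth across ten seeds — a regression floor for the pipeline,
not a claim about real data.

## Augmentation

Three bespoke operators plus the standard set expand ~100 annotated cubes
into >= 1,000 training pairs (default recipe: 2 CutMix + 2 histogram
matching + 2 local contrast + 4 standard derivatives per axon cube).

* **CutMix** pastes an axis-aligned random sub-box of the artifact cube
  (relative volume about `frac`, per-axis extents drawn with geometric mean
  `frac^(1/3)`) into the axon cube and clears the annotation inside the
  box.  Every output voxel equals the corresponding voxel of exactly one
  source.  Only artifact-into-axon pasting is implemented; the reverse
  direction would create cubes that are mostly artifact with a sliver of
  axon, which the artifact pool already represents.
* **Histogram matching** transfers background appearance: a monotone
  quantile mapping computed from the source's background voxels
  (annotation == 0) onto the reference's histogram, applied to background
  voxels only.  Annotated axon intensities are preserved bit-exactly —
  the concrete reading of "preserving the annotated axons".
* **Local contrast** scales the intensities of a random subset of the
  26-connected components of the annotation by a factor drawn from a
  range; everything else, including the annotation, is untouched.
* **Standard operators**: rotation and scaling resample intensity
  (trilinear) and annotation (nearest neighbor, re-binarized) identically,
  about the cube center and within the original shape; Gaussian noise,
  blur and brightness act on intensity only.

Every output records its operator chain, and replaying the chain from the
sources reproduces the output bit-exactly (asserted in the tests).  All
per-output seeds and partner choices derive from one master seed.

## Metrics

Volumetric Dice is `2|P ∩ G| / (|P| + |G|)`; two empty masks score 1 so a
perfect empty prediction is not penalized.  The centerline-aware scores use
the same skeletonization as the annotation pipeline, so metric and
annotation share one centerline definition: ClPrecision is the fraction of
the predicted skeleton inside the true volume, ClRecall the fraction of the
true skeleton inside the predicted volume, and ClDice their harmonic mean.
Raw (unthickened) skeletons are used.  If exactly one mask is empty all
three scores are 0.  Region-wise reporting computes per-region Dice for
each brain, the median per region across brains, and the mean of the
per-region medians.  Landmark deviation is the per-pair Euclidean distance
in micrometers given the voxel spacing.

## The loss family

Every loss is a pure, deterministic function of arrays.  Sign conventions
are unified so that every similarity is a loss to minimize (mutual
information and cross-correlation are negated); sum-versus-mean reductions
follow the published forms (the axon segmentation loss is a mean over
voxels; the outline and multiview losses are sums), each with an explicit
reduction option.

* **Axon segmentation**: weighted sigmoid binary cross-entropy on raw
  logits with positive-class weight 3 on axon voxels — so an axon voxel at
  probability 0.5 costs exactly three times a background voxel (the first
  acceptance quantity).  Log-sigmoid is evaluated in a numerically
  stabilized form.
* **Style transfer**: the adversarial value from discriminator scores, the
  two-directional mean-L1 cycle-consistency loss, and the summed outline
  BCE (probabilities at exactly 0/1 are clamped by epsilon with a
  warning).
* **Multiview semi-supervision**: the summed supervised BCE, the quadratic
  consistency loss between unannotated predictions and their mapped-back
  pi-rotated copies, and the 3D multiview term between coronal and
  horizontal-transformed-to-coronal predictions; the per-view loss is
  supervised + consistency with the two views weighted equally, and the
  total is coronal + horizontal + 3D.
* **Registration similarities**: mutual information over a joint
  histogram with 32 equal-width bins and natural logarithm (neither is
  specified in the published form; these are the package's defaults);
  local cross-correlation over 9^3 windows (clipped at faces,
  zero-variance windows contribute 0); and root-mean-square difference.
  The joint histogram is accumulated with linear partial-volume weights
  and symmetrized, so the MI loss is exactly symmetric in its arguments
  and varies continuously when either grid is resampled — with hard
  binning the loss would be piecewise constant in the transform
  parameters and numerically ungradable.
* **Affine penalties**: the identity penalty `||A - I||_F^2 + ||b||_2^2`,
  and the scaling penalty, by default `|det(A) - 1|`.  The literal printed
  form of the scaling constraint is `|rank(A) - 1|`, which is
  integer-valued and equals 2 for every invertible matrix — uninformative
  for its stated purpose of constraining brain scaling — so the
  determinant reading is the default and the literal form is retained
  behind `mode = "literal_rank"`.
* **Field penalties**: mean-L1 forward-difference gradient norm
  (smoothness), and inverse consistency: the rms difference between the
  registered image and itself resampled through the approximate inverse
  field `Phi^-1 = (-Phi_z o Phi, -Phi_y o Phi, -Phi_x o Phi)` (each
  component sampled at the displaced positions and negated, positions
  clamped at the grid).  The first-order inverse is accurate in proportion
  to the field's gradient: the tests verify a composition residual below
  10% of the field's rms norm on gently varying fields within the
  |Phi| <= 2 voxel regime.

The multi-constraint objective is the weighted sum of per-channel
similarities — MI for the original brain (70%), LCC for the style-proxy
brain (15%), rms difference for each region mask (15% split evenly; the
per-region split is unspecified in the source and even weighting is the
neutral choice) — plus the stage penalties: identity + scaling for the
affine stage, smoothness + inverse consistency (evaluated on the
highest-weight channel) for the deformable stage.

## Registration by direct optimization

The published registration is a trained network; its transferable
contribution at desk scale is the *objective*, not the trained predictor.
axocarto therefore realizes registration as direct per-pair optimization of
that objective: rigid (6 parameters: Euler z–y–x rotation about the grid
center + translation), affine (12 parameters), and a deformable stage
optimizing a control-point displacement field trilinearly upsampled to
voxel resolution.

* **Pyramid**: 3 levels, factor 2, block-mean downsampling (masks by
  majority so they stay binary); 320 x 456 x 528 maps to 160 x 228 x 264
  and 80 x 114 x 132.  Rigid and affine are fitted at the coarsest level
  only and applied, not re-fitted, at finer levels, following the
  published multiscale schedule.  The deformable field is optimized
  coarse-to-fine over the two coarsest levels by default, each coarser
  solution (displacements doubled, positions halved) initializing the
  next, and the final field is upsampled to the reference grid.
* **Preprocessing inside the objective**: intensity channels are min-max
  normalized per level (the network equivalent is input normalization);
  region masks are softened by a sigma = 1 voxel Gaussian so the mask
  channels carry gradient information — hard masks give a piecewise
  constant rms term.  The affine penalties are evaluated with the offset
  normalized by the grid half-extent, the analogue of a network operating
  on normalized coordinates; their weight defaults to 0.01, a gentle
  regularizer chosen so the penalties break ties without biasing
  parameter recovery.
* **Optimizers**.  Rigid and affine use L-BFGS-B with forward-difference
  numerical gradients; the affine stage adds a Nelder–Mead refinement,
  because the partial-volume binning makes the objective piecewise smooth
  and a simplex search recovers the last fraction of a percent — needed
  for 2% scale recovery, but not for the much looser rigid tolerances —
  that finite-difference gradients cannot resolve below the kink scale.
  The affine offset is parameterized in half-extent units so all twelve
  parameters move on comparable scales.  The deformable stage uses
  monotone gradient descent with backtracking line search and
  central-difference gradients: central differences are unbiased at the
  kinks of the L1 smoothness penalty (a one-sided difference at zero sees
  only the upward slope and would pin the field there), and a
  function-only line search matters because R's L-BFGS-B evaluates the
  gradient — here, one objective evaluation per control parameter — at
  every line-search point.  Steps that would make the affine determinant
  non-positive are rejected through a barrier.  Objective traces record
  the best value so far and are non-increasing by construction; the
  descent contract (result no worse than the initialization) is enforced
  explicitly.
* **Transform semantics**: `AffineTransform3D` is the forward point map
  `y = A x + b`; volumes are warped by pulling back through the inverse
  map, and deformation fields live on the reference grid with the
  pull-back convention (the warped image samples the moving image at
  `q + Phi(q)`).  Points map forward through the affine maps and through
  the approximate inverse field.  Stage composition order is rigid, then
  affine, then field.

**Problem sizes.**  The recovery experiments in the test suite run on
(80, 114, 132) phantoms with six regions for the headline checks (rigid
recovery of a 5-degree / 3-voxel perturbation within 1 degree and 1 voxel;
affine scale recovery of diag(1.1, 0.95, 1.05) within 2%; end-to-end
improvement of mean region Dice and landmark deviation after a combined
rigid + smooth nonrigid perturbation, with additive intensity noise on the
source), and on smaller phantoms (about 32–48 voxels per axis, 3–4
regions) for the per-stage unit tests.  Default iteration caps (40 rigid,
40 affine, 10 + 1 deformable) are sized to these problems; they are
configuration, not algorithm.

## Region quantification

Density is defined as the axon-voxel fraction of a region's support —
unit-free and in [0, 1]; raw counts are emitted alongside, since the
published reports do not state a normalization.  Hierarchy rollups sum
counts bottom-up (deepest regions first) so every parent row contains its
own plus all descendants' voxels, with densities recomputed from rolled-up
counts; the operation is idempotent and errors on cyclic parent links.
Points are assigned to regions by nearest-voxel lookup; out-of-bounds
points count under a sentinel id with a warning.  Heatmaps are Gaussian
smoothings of the binary axon map (mass-conserving away from faces;
kernels renormalized at faces so constants stay constant) with
maximum-intensity projections in the three anatomical views.

## Degenerate inputs and edge behavior

Empty masks skeletonize to empty; both-empty metric pairs score 1 and
one-empty pairs 0; constant cubes binarize to empty masks with a warning;
an empty annotation makes local-contrast augmentation a warning no-op; a
reference with fewer than two distinct values cannot be histogram-matched;
label volumes refuse trilinear interpolation; degenerate (single-bin)
mutual information is 0 with a warning; pyramid levels that would fall
below 2 voxels on an axis are an error; non-invertible affines
(determinant <= 0) are errors at construction and barriers during
optimization.

## Known limitations

* Whole brains are processed in memory; there is no out-of-core backend,
  so full-resolution 2,000^3-voxel volumes are out of scope.
* The thinning-based skeleton depends weakly on the order of the six
  directional subiterations (see above); all centerline metrics share
  this property.
* The first-order field inverse degrades for fields with large gradients;
  the inverse-consistency penalty discourages exactly that regime.
* The deformable stage's control-point resolution (spacing 10 coarsest
  voxels by default) bounds the recoverable warp frequency; warps finer
  than the control spacing are projected onto the control basis.
* Registration quality statements are phantom-level: real LSFM brains add
  modality gaps, damage and texture that only the trained-network pipeline
  addresses.
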