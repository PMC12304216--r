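---
title: "Automated vessel reconstruction for 3D MR-VWI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated vessel reconstruction for 3D MR-VWI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Three-dimensional MR vessel-wall imaging (3D MR-VWI) of the head and neck
acquires several co-registered sequences with complementary contrast:
bright-blood TOF-MRA, where flowing blood is bright and delineates the patent
lumen, and black-blood T1WI / contrast-enhanced T1WI-CE, where lumen signal is
suppressed and the wall — including occluded segments filled with thrombus or
enhancing tissue — remains visible. Clinical review of these images relies on
curved planar reformation (CPR): resampling the volume along each artery's
centerline so the whole curved vessel appears in a single planar image.
Producing those centerlines by hand is slow; **vwikit** automates the chain

> multi-sequence segmentation and recognition → centerline extraction →
> gap bridging and refinement → straightened CPR → quality metrics

and ships a synthetic vascular phantom generator so every stage is testable
without clinical data, which cannot be redistributed.

## Phantoms: what they emulate and what they do not

A phantom (`phantom_spec()`, `generate_phantom()`) is a set of tubular
branches — natural cubic splines through control points, arc-length resampled
at a quarter of the smallest voxel size, rasterized as the union of spheres
with the local radius. Scene builders provide the canonical study conditions
used throughout the tests: a 64^3 grid at 0.6 mm isotropic voxels (a typical
small head-neck VWI field of view), carotid-calibre radii (CCA ≈ 3 mm,
ICA ≈ 2.2 mm, ECA ≈ 1.8 mm), left/right bifurcation scenes with seeded
positional and radius jitter, and per-sequence mean intensities giving
bright-lumen TOF contrast and dark-lumen black-blood contrast with additive
Gaussian noise (σ = 5 against lumen/background separations of ~100
intensity units). Occluded spans take the background level on TOF (the
segment disappears from the angiogram) and a bright wall-like level on the
black-blood sequences, emulating the clinical appearance of fresh thrombus or
an enhancing occluded segment, without modelling thrombus age.

Branches of different arteries may only overlap near their ends (a
`junction_mm = 6` window), where parent and daughter vessels genuinely meet;
the geometrically closer branch claims the voxel, and mid-course crossings are
an error so ground truth stays unambiguous.

Deliberately **not** modelled: coil sensitivity profiles and bias fields, flow
and pulsation artifacts, inter-sequence misregistration, vessel wall
thickness, pathology other than occlusion, and the small distal intracranial
branches. Tests passing on phantoms therefore demonstrate the geometry and
learning machinery under controlled conditions; they do not certify clinical
performance.

The augmentation suite (`augment_phantom()`) applies the four training-set
operations — integer-voxel displacement, field-of-view truncation, left-right
reversal with exact side-label swap, and simulated occlusion — as paired
transforms of volumes, mask and centerlines. The default configuration emits
six samples per input: the original, one of each operation, and one composed
displacement-then-flip. Four operations admit several compositions reaching a
six-fold expansion; the displacement∘flip composition was chosen because both
constituents are exact (no resampling), and it is recorded in the
configuration object.

## Segmentation networks

`build_model()` constructs the 3D segmentation-and-recognition network: an
input convolution merging the input sequences, four down-sampling units
(stride-2 convolutions) each followed by a bottleneck residual block, four
up-sampling units (stride-2 transposed convolutions) whose outputs are
concatenated with the same-scale encoder features and fused by a residual
block, and a 1×1×1 convolution head producing per-voxel class scores over
background plus artery classes. Recognition is per-voxel multi-class: the
argmax label *is* the artery identity, which keeps segmentation and
recognition in a single head.

Design choices where the architecture family leaves freedom:

* **Bottleneck residual blocks** are pre-activation
  IN → ReLU → 1×1 reduce (to a quarter of the output width) → IN → ReLU →
  3×3×3 → IN → ReLU → 1×1 expand, added to the (1×1-projected, when widths
  differ) input.
* **Down/up-sampling** by stride-2 convolution and stride-2 transposed
  convolution (kernel 2), rather than pooling/interpolation.
* **Skip merging** by concatenation followed by a residual block.
* **Instance normalization** inside every block; statistics are per-channel
  over the spatial grid of the single instance.
* **Coordinate channels.** Three normalized absolute-coordinate channels are
  appended to the input internally. Training is patch-based, and a purely
  translation-invariant network cannot distinguish left from right artery
  segments inside a small crop; the coordinate channels carry the positional
  information that full-volume context would otherwise provide. The
  configuration's `in_channels` continues to count input *sequences* (1 for
  the bright-blood TOF path, 2 for the black-blood T1WI/T1WI-CE path).

The implementation is native R/C++: im2col and scatter/gather primitives in
C++, BLAS matrix products, and hand-derived backward passes for every layer
(validated against finite differences to ~1e-8 relative error in the test
suite).

**Sequence fallback** (`prepare_channels()`): with both black-blood sequences
present, channel 1 = T1WI and channel 2 = T1WI-CE, and the output frame is
fixed to channel 1 (a second channel on a different grid is resampled onto
it). With only one black-blood sequence it is duplicated into both channels.
TOF-only input activates the single-channel bright-blood path. Intensities
are z-scored within a body mask (voxels above 10% of the intensity range).

**Training** (`train_model()`): Dice-loss supervision with Adam
(first-moment coefficient 0.9, initial learning rate 1e-3, weight decay
1e-5, exponential learning-rate decay — the decay rate being a choice the
optimiser family leaves open). Three adaptations make patch-based training
at desk scale behave, and each addresses a failure we observed directly:

* the training Dice average includes the background class — with several
  artery classes and foreground-only averaging, every crop that pushes one
  class down on background voxels passively pushes the others up there
  (softmax coupling) and the background class collapses;
* an auxiliary cross-entropy term (weight 0.5) supplements the Dice term —
  soft Dice gives exactly zero gradient to classes absent from a crop, so
  small crops let probability leak onto absent artery classes; full-volume
  batches (where every class is present in every step) never see this, small
  crops always do. The exported `dice_loss()` itself keeps the plain
  foreground-averaged contract;
* gradients are clipped to unit global norm — a crop containing a sliver of
  foreground makes the Dice denominator tiny and the gradient explodes.

Crops are drawn from the same half-overlap tiling that inference uses
(vessel-containing tiles with probability 0.9), and prediction runs as
sliding windows of the training patch size with probability averaging:
instance-normalization statistics then match exactly between training and
inference (full-volume single-pass inference on a patch-trained model
degrades badly, since the normalization statistics shift). Validation
evaluates held-out volumes this way and the parameters with the best
validation foreground Dice are returned.

**Fusion** (`fuse_segmentations()`): on a shared grid, the fused label is the
argmax over the per-class maximum of the two probability maps — except at
occlusion-candidate voxels, foreground under the black-blood model but
background under the bright-blood model, where the black-blood label wins.
This preserves occluded segments invisible on TOF. The rule is symmetric up
to that one documented exception, and `fuse(x, x) = x`.

## Centerline geometry

**Distance field.** Exact Euclidean distance-to-background in mm (separable
parabola-envelope transform with anisotropic spacing).

**Skeletonization** (`skeletonize()`) is distance-ordered homotopic thinning:
voxels are deleted in increasing distance-field order whenever deletion
preserves topology — the simple-point test uses the standard characterization
(exactly one 26-connected foreground component in the 26-neighbourhood, and
exactly one 6-connected background component among the 18 face/edge
neighbours touching a face) — producing a centred, one-voxel-wide,
topology-preserving curve skeleton. Plain homotopic thinning of a
contractible tube would retract its ends without bound, so *anchors* pin the
medial extremities: per connected component, the distance-field maximum seeds
a geodesic distance map, and voxels that locally maximise
(geodesic distance + 2 × EDT), restricted to medial voxels (EDT ≥ 60% of the
component maximum), are non-deletable, as is the seed itself. Unanchored
strand ends retract, so skeleton ends land on medial extremities rather than
on arbitrary frozen endpoints.

**Graph decomposition** (`principal_centerlines()`): skeleton voxels with
26-adjacency form a graph; 26-adjacency edges that close a triangle are
staircase shortcuts and are dropped (longest first); genuine cycles — possible
when a segmentation error creates a handle — are broken at the node with the
smallest distance-field value, with a warning. Spurs shorter than
`prune_len = 3` mm hanging off junctions are pruned (the paper family is
silent on pruning; 3 mm is below any artery calibre of interest). Maximal
junction/endpoint paths become centerlines, ordered inferior → superior, with
the side taken from the mask labels under the path (majority vote) or, when
unlabelled, from the component's position relative to the mid-sagittal plane
(+x is the subject's left).

**Path tracing** (`trace_path()`): Dijkstra on the 26-connected grid with
edge cost `step_mm / (field + ε)`, ε = 0.1 mm — the reciprocal-distance cost
keeps paths on lumen-central voxels while ε bounds the cost of boundary and
background voxels. Cost ties resolve by voxel order, so traces are
deterministic. The implementation is checked against an independent
exhaustive shortest-path oracle on small grids.

**Bridging, extension and junction handling** (`connect_and_extend()`).
Terminal segments are first extended greedily uphill in the distance field
(stopping below one voxel of field value, with the total capped at the local
radius plus two voxels — the scale of thinning retraction); when the label
mask is supplied the walk may cross unlabelled voxels (an occlusion gap) but
never another artery's territory, so it cannot crawl through a junction.
Fragments of the same artery and side whose endpoints lie within
`max_bridge = 10` mm are then joined by path tracing through the field. This
is how occlusion gaps are reconnected: the bridging field comes from the
black-blood-visible lumen, where the occluded segment is still traceable
even though it is invisible on TOF. Larger gaps stay separate and are
flagged `incomplete`.

Junctions need two corrections, both driven by the anatomical adjacency
table (CCA–ICA, CCA–ECA, ICA–MCA/ACA, VA–BA, BA–PCA; an editable YAML
file). A daughter artery's voxel territory begins a little above the
junction — the parent, being wider, claims the shared lumen — so each
daughter line is extended to the nearest point on its parent (preferring the
parent's end, the bifurcation apex) by path tracing; daughters whose parent
never comes within `max_bridge` are flagged `incomplete`. Conversely the
parent keeps a thin sliver of territory between its daughters that
skeletonizes into a short spike past the apex; at the end where daughters
attach, parent points whose own-label medial depth falls below 75% of the
line's maximum are trimmed, bounded to one local radius of arc.

**Lumen refinement** (`refine_with_lumen()`): each point is re-centred to the
centroid of its lumen cross-section in the plane normal to the local tangent.
Because a far-off-centre point sees only part of its section, the centroid
step is iterated (3 sweeps, sampling radius = local field value + 2 voxels at
half-voxel resolution), followed by a 5-sample moving-average smoothing with
fixed endpoints. Points with an empty cross-section (e.g. across an occlusion
bridge) are kept unmoved and the line flagged `unrefined-span`; if more than
half the line lies outside the lumen, refinement is refused with a warning.

## Curved planar reformation

`straightened_cpr()` resamples the centerline at a uniform arc-length step
(default: the smallest voxel size), transports a frame along it by the
double-reflection rotation-minimizing method — Frenet frames are undefined on
straight segments, which vessels frequently contain — and samples the volume
trilinearly along the in-plane direction rotated by `angle_deg` from the
transported normal, within ±`half_width_mm`. Rows are arc-length samples;
out-of-volume samples take the padding value (volume minimum by default) and
are flagged. The initial normal is the world axis least aligned with the
first tangent, making images reproducible run to run.

## Quality metrics and the quantitative rubric

* `dice_coefficient()`: 2|X∩X̄|/(|X|+|X̄|); two empty sets score 1 by
  convention (perfect agreement about absence).
* `centerline_accuracy()`: the arc length of the extracted line lying within
  `tol_mm` of the truth polyline, divided by the truth length, capped at 1.
  "Accurately extracted" is operationalized as within-tolerance distance with
  `tol_mm = 1` by default, surfaced as a parameter.
* `mcd()`: the symmetric average of the two directed mean nearest-neighbour
  distances between centerline point sets. Centerline inputs are resampled at
  0.5 mm first — the raw value would depend on control-point density — with
  the step exposed as a parameter.
* `deviation_fraction()` + `rubric_score()`: the mechanized 4-point quality
  rubric. Deviation is the fraction of the line's arc length outside the
  target lumen (arc-length fraction was chosen over lateral distance, which
  the verbal rubric leaves ambiguous, and is documented as such):
  0 → score 1, (0, 25%] → 2, (25%, 50%] → 3, above 50% or an unrecognised
  vessel → 4. The human criteria (artifact severity, diagnostic clarity) are
  explicitly out of scope of this quantitative surrogate.

## Problem sizes used by the test suite

The package's tests and the acceptance script run the geometry suite on
64^3 phantoms, exercise metric oracles on grids up to 12^3 and point sets up
to 200, and train at reduced scale: a two-sample overfit check (16^3 tiles,
3000 steps) and a 20-train / 5-validation bright-blood run at 64^3 — the 20
training phantoms expanded six-fold by the augmentation suite, 60 epochs of
16^3 tile crops, validation every 10 epochs with best-model selection — with
a pinned seed. These sizes were chosen so the whole suite completes on a
single CPU in minutes while still exercising every code path end to end; the
training runs demonstrate that the learning machinery optimises the intended
objective, not that a clinically accurate model results at this scale.

## Known limitations

* The thinning anchors assume tubular components of roughly uniform calibre
  per label; plate-like structures (not present in vascular masks) would
  skeletonize to curves, not medial surfaces.
* Gap bridging joins fragments pairwise by nearest endpoints; pathological
  fragment layouts (three collinear fragments with interleaved gaps) merge in
  greedy order.
* The DICOM reader supports uncompressed implicit/explicit VR little-endian
  single-frame series — the common export for MR — not compressed transfer
  syntaxes or multi-frame objects.
* Orientation handling assumes axial, axis-aligned acquisitions; the
  orientation matrix is recorded but oblique volumes are not reoriented.
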