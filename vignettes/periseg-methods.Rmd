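---
title: "Methods: perioperative segmentation reporting and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: perioperative segmentation reporting and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(periseg)
```

## Scope and model

`periseg` implements the computational pipeline that surrounds a trained
brain-tumor segmentation network in a perioperative reporting system. The
network itself is deliberately out of scope: it enters only through the
`patch_predictor` contract — a deterministic callable mapping a
multi-channel image patch to same-shape voxel probabilities in [0, 1].
Everything else is implemented and tested here: preprocessing,
whole-volume probability assembly, postprocessing, cross-structure
refinement, standardized reporting, and a three-level validation
framework. The anatomical vocabulary is the perioperative standard: tumor
core (TC, enhancing tissue plus necrosis/cysts), non-enhancing tumor core
(NETC), surrounding non-enhancing FLAIR hyperintensity (SNFH),
postoperative enhancing residual tissue (ET), and the resection cavity.

## Preprocessing

The chain runs in a fixed order: (i) resampling to isotropic spacing
(default 1 mm; output shape `round(shape · spacing / target)`), (ii) tight
cropping to the bounding box of above-background voxels, (iii) difference
channels (`t1d = t1c − t1w`, computed before intensity normalisation so
true enhancement survives with its sign), (iv) clipping to the [0th,
99.5th] percentile, (v) normalisation of nonzero voxels.

Three choices here were genuinely open and are resolved as follows:

- *Normalisation scale.* "Zero-mean normalisation of nonzero values" is
  implemented as zero-mean **and unit-variance** over the voxels that were
  nonzero before normalisation, which is the standard practice for MR
  network inputs; the division by the standard deviation can be switched
  off (`unit_variance = FALSE`). A constant nonzero foreground is
  mean-subtracted only (scaling would divide by zero) with a warning.
- *Percentile statistics* are computed over **all** voxels, zeros
  included, with type-7 (linear interpolation) quantiles. Background
  voxels are exactly zero in this pipeline, so including them only shifts
  the lower percentile, which is 0 anyway.
- *Interpolation.* Trilinear for intensities, nearest-neighbour for masks
  (preserves binarity). Grids are centre-aligned, so resampling a volume
  onto its own spacing is the identity.

## Probability-map assembly and postprocessing

Sliding-window inference tiles the (zero-padded, if smaller than one
patch) volume with a fractional overlap (default 50%, i.e. stride = half
the patch per axis, with a final window flush against each border).
Overlapping predictions are fused by **unweighted mean** — the simplest
contract that is exactly testable; Gaussian window weighting was
considered and rejected because it changes results only near window seams
while making the fusion untestable in closed form. A voxel-wise-defined
predictor is therefore reproduced exactly for any overlap, which the test
suite exploits.

Test-time augmentation runs one pass per enabled transform (axis flip,
axial 90° rotation, gamma contrast) plus the identity pass; geometric
transforms are inverted on the predicted map before averaging, gamma needs
no inversion. Transform parameters are sampled once from the
configuration seed, so TTA is reproducible. Model ensembling combines one
to five maps voxel-wise by mean (`average`) or maximum (`amax`).

Postprocessing is two steps: zero all probability outside the brain mask,
then binarize at the operating threshold, label 26-connected components,
and zero the probabilities of components smaller than 0.05 ml **or** not
visible on at least two consecutive axial slices. Because a 26-connected
component occupies a contiguous slice range, "consecutive" reduces to
"at least two distinct slices". The component analysis runs at the same
threshold later used for reporting; since surviving probabilities are
untouched, the operation is idempotent.

## Refinement

Independently produced masks are made globally consistent. For
contrast-enhancing tumors, preoperatively: TC is the reference and is
never modified; NETC is intersected with TC; TC is subtracted from SNFH;
WT is the now-disjoint union TC ∪ SNFH. Postoperatively ET is the
reference; cavity and ET are subtracted from SNFH **jointly** (as a
union), which makes the result order-independent by construction. For
non-enhancing tumors SNFH itself is the whole tumor, minus the cavity
postoperatively. ET/cavity overlaps have no defined resolution rule and
are left untouched but flagged in the report warnings. All outputs are
clamped to the brain mask when one is present; refinement is idempotent,
which the suite verifies on randomized overlapping structure sets.
Preoperative NETC is not additionally subtracted from SNFH: NETC ⊆ TC
after refinement, and TC is already subtracted, so the exclusion is
implied.

## Reporting

Per structure and timepoint: volume (voxel count × voxel volume),
diameters on the **axial slice of maximal in-slice area** — the
bidimensional convention of response assessment — and the tumor-to-brain
volume ratio in percent. Diameters are: area-equivalent diameter
`2·sqrt(area/π)`; Feret diameter as the maximal point-pair distance over
the convex hull of pixel centres; long/short axes from the second central
moments of the slice region (the axes of the moment-matched ellipse,
`4·sqrt(λ)`). For annular regions (an SNFH halo) the moment-matched long
axis can exceed the Feret diameter; both are reported, they answer
different questions. A single-pixel slice reports its equivalent diameter
and zero axes. 3D diameter alternatives were rejected as inconsistent
with the slice-area convention.

Volumetric evolution is `100·(pre − post)/pre` percent — the extent of
resection when the structure is the tumor; a zero preoperative volume
yields `NA` (not applicable), and complete removal yields exactly 100.
The surgical category compares the postoperative residual (ET for
contrast-enhancing tumors, SNFH as the whole-tumor proxy otherwise)
against **policy** thresholds: `complete` below 0.175 ml — the residual
tumor detectability cut-off, reused because the response-assessment
guidelines do not print explicit bounds — and `near total` up to a
configurable 1 ml. Both are fields of `threshold_policy()`, echoed into
every report, and never hard-coded. Atlas-based location features are out
of scope (they require registration); the report carries an explicit
"unavailable" placeholder. Reports serialize to JSON with sorted keys and
fixed precision, so identical inputs give byte-identical files.

## Validation framework

Evaluation binarizes a probability map at ten equally spaced thresholds
k/10, k = 1..10 (threshold 0 would binarize everything and is excluded);
masks are nested by construction. Per threshold and sample:

- **Patient-wise**: a side is positive when its volume reaches the
  structure's cut-off (ET 0.175 ml, NETC 0.05 ml, cavity 0.1 ml, TC
  0.1 ml); the same rule applies to ground truth and prediction. Both
  positive count as TP only when Dice exceeds the policy threshold
  (default 0.1%). Recall, precision, specificity and balanced accuracy
  follow, with undefined denominators reported as `NA` rather than
  raised.
- **Voxel-wise**: Dice, recall, precision (percent) and HD95 — the
  maximum of the two directed 95th-percentile surface distances in mm,
  computed from Euclidean distance transforms that honour anisotropic
  spacing. Two empty masks agree perfectly (Dice 100, HD95 0) but are
  excluded from positive-sample aggregates; one empty operand gives Dice
  0 and undefined HD95.
- **Object-wise**: 26-connected components below the per-structure
  minimum size (75 voxels; 50 for NETC) are discarded on both sides;
  survivors are matched one-to-one by the Hungarian algorithm with cost
  `1 − Dice`, and zero-overlap assignments are dissolved. Each unmatched
  ground-truth component contributes 0 to Dice and recall, each unmatched
  prediction 0 to Dice and precision; HD95 averages over matched pairs
  only (including unmatched components would require an arbitrary
  distance convention).

Pooled cross-validation estimates are exact: the size-weighted mean and
the variance decomposition
`[Σ(nᵢ−1)sᵢ² + Σnᵢ(mᵢ−m̄)²]/(Σnᵢ−1)` reproduce the sample statistics of
the concatenated per-sample values to numerical precision. The operating
threshold maximizes mean voxel-wise Dice over positive samples, ties
broken toward the higher (stricter) threshold. The sensitivity analysis
re-runs the patient-wise classification with the TP Dice threshold swept
over {0.1, 10, 25, 50, 75}%; volume positivity is unaffected, so TN and
FP rows are constant and TP is non-increasing.

## Synthetic phantoms

The generator emulates the perioperative imaging situation with
ellipsoids and spheres: an ellipsoidal brain; preoperatively a spherical
TC whose interior fraction is NETC and whose surrounding shell is the
SNFH halo; postoperatively a CSF-like cavity replacing most of the core,
1–3 small ET fragments seeded on the cavity margin (volumes spanning the
0.175 ml cut-off by design), and a shrunken halo. Sequences are
piecewise-constant tissue intensities (t1c rim bright, cavity dark,
SNFH bright on FLAIR/T2) plus Gaussian noise; the background outside the
brain is exactly zero. Masks with a requested volume are built by taking
the k voxels nearest a centre with `k = round(volume·1000)`, so realized
volumes match requests to half a voxel and small-volume bisection
experiments are exact.

What the phantoms deliberately do **not** model: MR physics (bias fields,
partial volume, susceptibility), anatomy (atlases, ventricles), pathology
texture, or registration error. Consequently, passing tests demonstrate
the correctness of the *computational* pipeline — metrics, refinement,
reporting, assembly — not segmentation performance on clinical data,
which requires trained networks and real cohorts.

The oracle patch predictor closes the loop: it serves the (optionally
blurred and noise-corrupted) ground-truth indicator through the
`patch_predictor` contract, so with zero corruption the assembled,
thresholded map must reproduce the mask bit-for-bit — the pipeline's
end-to-end identity test. `perturb_mask` provides graded corruption
(metric-ball dilation/erosion, translation, component dropping, false
components) whose mean Dice decays monotonically with severity, used to
verify that the metrics order degraded predictions correctly.

## Problem sizes and numerical choices

The default phantom grid is 96³ at 1 mm, chosen so the full five-patient
demonstration pipeline runs in well under two minutes on one CPU; tests
that need whole cohorts use 64³ phantoms with proportionally smaller
structures, and patch-based tests use 16³–64³ patches (patch shape is a
predictor property; the 160³ clinical default exceeds a phantom).
Distance transforms use the exact separable lower-envelope algorithm with
per-axis spacing; an all-background mask transforms to `Inf`. Quantiles
are type 7 throughout. Component connectivity is 26 (the most permissive
3D standard) everywhere. Bounding boxes are 1-based inclusive on the R
side; patch offsets are 0-based grid coordinates. Ties in the
nearest-k-voxel mask builder are broken by array order, making every
phantom bit-reproducible from its seed.

## Known limitations

- The classifier stages of a deployed system (MR-sequence and tumor-type
  identification) are interface points here; the default implementation
  reads labels from the cohort manifest.
- Object-wise HD95 ignores unmatched components; comparisons against
  frameworks that penalise them numerically will differ on fragmented
  predictions.
- Registration, skull stripping, bias-field correction and DICOM
  ingestion are explicitly out of scope; inputs are assumed co-registered
  NIfTI with a supplied brain mask.
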