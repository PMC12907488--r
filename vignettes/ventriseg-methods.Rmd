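---
title: "Methods: cascaded detection and segmentation for ventricular volumetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cascaded detection and segmentation for ventricular volumetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ventriseg)
```

## The problem and the approach

Ventricular volume is a central quantity in hydrocephalus care: serial CT
scans are compared to decide whether ventricles are enlarging, and classical
linear indices (such as the Evans index) are sensitive to head pose and slice
selection. `ventriseg` implements a fully automatic two-stage pipeline that
replaces linear measurements with subregion-level volumetry of the twelve
parts of the ventricular system — the body, anterior horn, atrium, posterior
horn and temporal horn of each lateral ventricle, plus the third and fourth
ventricles.

The cascade works slice by slice on a standardized volume:

1. **Preprocessing** — the native CT is reoriented to a fixed anatomical
   convention, resampled to isotropic 1 mm voxels into a cubic grid (256³ by
   default), CSF-windowed from 0 to 80 HU into `[0, 1]`, and cut into axial
   slices.
2. **Detection** — a per-slice object detector proposes one bounding box per
   subregion per slice.
3. **ROI geometry** — each box is enlarged (3× by default, about its
   center), cropped, zero-padded to a square and resized to a standardized
   patch; every geometric parameter is recorded in a `crop_transform` so the
   operation can be inverted exactly.
4. **Segmentation** — a per-subregion 2D U-Net predicts a binary mask on the
   patch. Eleven models cover the twelve classes: the scarce left and right
   posterior horns share one model, trained on pooled patches after
   mirroring the right side into left chirality.
5. **Backsampling** — predicted masks are pushed back through their inverse
   crop transforms, stacked into per-class 3D volumes, and fused into one
   exclusive label volume; subregion volumes in ml and relative volumetric
   errors (RVE, `(predicted − reference)/reference`) are reported per class
   and for the standard groups (whole system, left side, right side,
   midline; the side groups comprise anterior horn, body, atrium and
   temporal horn of that side).

The two-stage design matters because each segmentation model then sees a
highly homogeneous input — a zoomed, windowed patch containing exactly one
anatomical structure — so no further intensity normalization is needed.

## Tunable parameters

| Parameter | Default | Unit | Rationale |
|---|---|---|---|
| CSF window | 0–80 | HU | maximal CSF/ependyma contrast on head CT |
| canonical grid | 256 | voxel | 1 mm isotropic standard frame |
| enlargement factor | 3 | — | "up to 300 %" context around each box; a `+300 % ⇒ 4×` reading is available via `factor = 4` |
| crop mode | auto | — | square boxes within the target are pad-only (bit-exact invertible); all others pad to square and resize |
| segmentation threshold | 0.5 | prob. | conventional operating point of a sigmoid output |
| NMS IoU | 0.6 | — | detector validation operating point |
| confidence threshold | 0.001 | — | keep almost all candidates; low thresholds ensure no slice is missed |
| U-Net space | start 32–128, depth 3–5, blocks 2–5 | — | production hyperparameter ranges; desk-scale configs (`desk = TRUE`) may go below |

Adam is used as the optimizer with binary cross-entropy loss and rectified
linear activations (both fixed); learning rate (1e-3 or 1e-4), batch size
(32 or 64), dropout and batch normalization are configuration choices. The
probability threshold, optimizer and early-stopping policy are deliberately
exposed as configuration with the defaults above.

## The synthetic phantom

No public CT cohort accompanies the method, so the package ships a seeded
phantom generator (`phantom_spec()`, `generate_phantom()`,
`phantom_cohort()`): a bone ellipsoid shell (skull), noisy parenchyma
(35 ± 3 HU), and twelve CSF-filled subregions (8 ± 2 HU) modeled as
ellipsoids and curved tubes (torus arcs, for the thin posterior and temporal
horns) with closed-form volumes. Primitive volumes are anchored to the
magnitudes reported for shunted hydrocephalus cohorts: bodies ≈ 29 ml,
anterior horns ≈ 8.4 ml, atria ≈ 5.3 ml, temporal horns ≈ 3.4 ml, third
≈ 3.1 ml, fourth ≈ 1.9 ml, posterior horns ≈ 0.7 ml.

Ventriculomegaly is modeled as a dilation of the whole ventricular
constellation about its centroid: volumes scale exactly with the cube of the
factor, pairwise disjointness is preserved by construction at any scale, and
per-subject cohort draws (log-normal scale, clamped to `[0.7, 1.3]`; pose
jitter up to ±5° about each axis) stay inside the skull — verified over a
seeded sweep of the envelope. Analytic-vs-voxelized volume agreement is
within 3 % for every primitive whose smallest feature is at least 5 mm; the
4 mm-thin posterior-horn tube voxelizes more coarsely at 1 mm, which is the
expected behavior for sub-voxel-scale features.

What the phantom does **not** emulate: CT physics (beam hardening, streaks),
craniectomy defects, shunt hardware, anatomical shape variability beyond
scale and pose, and partial-volume texture at tissue interfaces. Passing
tests on phantoms therefore demonstrate that the *pipeline machinery* —
geometry, metrics, reconstruction, and the ability of the models to learn a
well-posed contrast — is correct; they do not certify clinical segmentation
accuracy on real scans.

## The built-in models

Re-implementing a 140-million-parameter production detector is out of scope;
the detector stage is a pluggable contract with three implementations:

* the **oracle detector** (boxes derived from ground-truth masks — the same
  box source the two-stage design itself uses to build its segmentation
  training set),
* an **external mode** consuming YOLO-format `.txt` predictions from any
  outside detector, and
* a **built-in CPU-trainable detector**: an encoder–decoder convolutional
  network with two skip connections that predicts a per-class sigmoid
  *support map* at full input resolution, trained with positively weighted
  binary cross-entropy against rasterized ground-truth boxes.

Three design details of the built-in detector deserve explanation:

* **Coordinate channels.** A small fully convolutional network is
  translation-equivariant: left and right homologues are locally
  indistinguishable, so lateralized classes need absolute position. Two
  normalized coordinate maps are appended to the input.
* **Flip augmentation swaps lateral classes.** Mirroring a slice turns
  right-sided anatomy into left-sided anatomy; flipping *without* swapping
  class ids teaches the detector systematic left/right confusion (the
  `lr_confusion_rate()` diagnostic measures exactly this failure mode).
* **FWHM box decoding.** Boxes are decoded from each above-threshold
  connected component as the interpolated half-peak crossings of the
  component's marginal max-profiles. For a saturated map this is the 0.5
  level set of `P(inside box)`; for small unsaturated bumps the full width
  at half maximum still estimates the extent. The level fraction is
  calibrated once, after training, on *training* slices only (recall
  maximizing); no held-out data is touched.

The segmentation U-Net is a standard encoder–decoder with skip connections:
`depth` levels of `blocks_per_level` 3×3 convolution blocks, filters
doubling from `start_filters` per level (bottleneck at
`start_filters · 2^depth`), nearest-neighbor upsampling, and a 1×1 sigmoid
output head. Both networks run on a small batched im2col/BLAS engine written
for this package; gradients are verified against finite differences in the
test suite, and seeded training is reproducible on CPU.

## Numerical choices

* **Interpolation** — trilinear for intensities (in HU space, before
  windowing), nearest-neighbor for labels and masks; mask resizing uses
  nearest neighbor so labels stay binary.
* **Canonical placement** — symmetric center crop/zero-pad per axis after
  isotropic resampling; the exact canonical-voxel→native-voxel affine is
  recorded and invertible.
* **Pixel conventions** — half-open integer pixel boxes, origin top-left,
  x = column, y = row; stated once in the ROI module and used everywhere.
* **Resize alignment** — output pixel `i` samples input coordinate
  `(i + 0.5)·n_in/n_out − 0.5` (pixel-center alignment), which makes the
  pad-only inverse bit-exact and the nearest up/down cycle lossless.
* **Empty-mask conventions** — Dice/Jaccard of two empty masks is 1.0
  (correct absence; flagged via an attribute), HD95 of an empty mask is
  missing, RVE with a zero reference is missing rather than infinite. These
  matter for posterior horns, which are genuinely absent in many subjects.
* **HD95** — surfaces are foreground voxels with a background face-neighbor
  (volume border counts as background); both directed surface-distance sets
  are pooled before the 95th percentile (type-7 quantile). Literature varies
  on pooling versus per-direction percentiles; the pooled convention is
  fixed here and checked against an exhaustive all-pairs oracle.
* **AP** — all-point interpolation (precision envelope); per-class
  aggregation averages over classes with at least one ground-truth instance.
* **Overlap fusion** — voxels claimed by several per-subregion models are
  assigned by fixed rarity priority (posterior horn > temporal horn >
  atrium > anterior horn > third > fourth > body) so small structures are
  not swallowed by large ones; the contested-voxel count is logged on the
  fused volume.
* **Box enlargement** — "up to 300 %" is read as a 3× scale about the box
  center, rounded outward, clipped to the slice.

## Desk-scale problem sizes

The test suite and the acceptance script exercise the full pipeline at
sizes a laptop CPU handles comfortably, chosen once and documented here:
phantoms on a 64³ grid with the head geometry scaled by 0.24 (the head fills
the frame in the same proportion as a real head in a 256 mm field of view),
mild ventriculomegaly spread (log-normal around 1.1) and ±4° pose jitter.
The U-Net learning check trains the pooled lateral-ventricle-body model on
~360 patches of 48 px (start 16, depth 3, one block — below the production
ranges, hence `desk = TRUE`) for 10 epochs and evaluates on held-out
subjects; the detector check trains on eight subjects' annotated slices at
64 px for 30 epochs with flip-only augmentation and evaluates recall on four
held-out subjects. End-to-end identity and resize-path checks run the
oracle detector with ground-truth mask passthrough, where the fused output
must equal the input labels bit-exactly (pad-only crops) or reproduce the
whole-system volume within 2 % (resize-mode crops, patch 48 so genuine
downsampling occurs).

## Known limitations

* The built-in detector and desk-scale U-Nets are deliberately small; they
  demonstrate that the cascade learns and are not a substitute for a
  production detector (the external YOLO-label mode exists for that).
* One box per class per slice is assumed (disjoint components of a class are
  merged); anatomy admits one instance per class per slice, but pathologies
  that fragment a subregion would violate this.
* Volumetry is computed on the canonical 1 mm grid; mapping back to native
  resolution through the recorded affine is possible but volumes are
  reported in the standardized frame, matching the fixed-resolution design.
* Axial-only slicing means transitions between subregions along the
  inferior–superior axis are the dominant error source — visible in the
  higher per-subregion RVE compared to grouped volumes.
* The DICOM reader covers single-frame, uncompressed little-endian CT
  series only; enhanced multi-frame DICOM and compressed transfer syntaxes
  are out of scope.
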