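---
title: "Quantifying condylar remodelling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying condylar remodelling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condylometry)
```

## The problem

After bimaxillary orthognathic surgery the mandibular condyle adapts to its
new mechanical environment. Most of this remodelling is physiological, but
its pathological extreme — condylar resorption, operationalised as a loss of
ramus height exceeding 6% of the pre-surgical value — causes relapse, open
bite and loss of posterior vertical dimension. Monitoring therefore needs
quantitative, reproducible measurements on the pre-operative (T0) and
follow-up (T1) CBCT scans rather than visual impressions.

`condylometry` implements a six-parameter digital workflow on T0/T1 imaging
of each condyle:

1. **Ramus height** (mm): distance from the highest point of the condylar
   head (`condyle_apex`) to the lowest point of the mandibular angle
   (`gonion_lowest`).
2. **Intercondylar angle** (degrees): at the anterior border of the foramen
   magnum, subtended by the centres of the maximum transverse diameter of the
   two condylar heads.
3. **Condylar axis inclination** (degrees): between the maximum transverse
   diameter line and the ramus major axis, after orthogonal projection onto
   the coronal plane.
4. **Condylar volume** (mm^3): voxel volume of the segmentation restricted
   to the region of interest from the apex to 15 mm down the condylar axis.
5. **Mean bone density** (HU): mean intensity over the same region.
6. **Articular surface change** (mm): per-region mean signed distance
   (apposition positive/red, resorption negative/blue) between the rigidly
   registered T0 and T1 surface meshes, over the anterior, posterior,
   medial, lateral and superior surfaces of the condylar head.

Parameters 1–3 are landmark-based; 4–5 are voxel-based; 6 is mesh-based.
The package also ships the per-patient values of a published 12-patient
(24-condyle) reference cohort, a cohort-statistics layer reproducing its
summary tables, and a synthetic phantom generator that provides exact ground
truth for every stage.

## Data model and conventions

All physical coordinates are millimetres in the DICOM patient frame (LPS:
+x left, +y posterior, +z superior). The centre of voxel `(i, j, k)`
(1-based R indices) is at `origin + (index - 1) * spacing`. NIfTI input,
which follows the RAS convention, is converted on load by flipping the
first two array axes as needed; only axis-aligned (non-oblique)
orientations are supported, which covers CBCT exports. DICOM reading
applies the rescale slope/intercept so intensities are always calibrated
HU; a series without rescale tags is assumed to already be in HU, with a
warning.

The per-condyle container is a `condyle_study`: volume, congruent binary
mask, surface mesh and named landmark set, all in one physical frame. The
required landmark names are documented in `?landmark_set`; a missing
landmark errors at measurement time (naming the landmark), not at load
time, so partially annotated datasets can still be used for the
measurements they support.

## Landmark morphometry

*Ramus height* is the Euclidean distance between the apex and gonion
landmarks. The clinical definition draws a tangent line to the ramus; with
two stored endpoints the tangency constraint is not enforceable, and the
two-point distance is what a 2D-line measurement tool reports in practice.
This is a deliberate operationalisation: it makes the measurement exactly
reproducible from the stored landmarks.

*Condylar axis inclination* is measured on the coronal projection because
the clinical measurement is drawn on coronal slices. We take the coronal
plane to be the plane orthogonal to the anterior-posterior axis of the
patient frame and project both lines orthogonally. The angle is reported
unsigned in [0, 180); pre/post deltas are signed by subtraction
(`T1 - T0`), so an intra-rotation and an extra-rotation of equal size give
opposite signs. A line that projects to (near) zero length — one running
almost exactly antero-posteriorly — raises a degenerate-geometry error
rather than returning an unstable angle.

*Resorption classification* uses the strict threshold: percent height
change `< -6` flags resorption. The boundary value −6.0 itself does not.

## Volumetrics and densitometry

The region of interest is a half-open slab: foreground voxels whose centres
project onto the condylar axis within `[0, 15)` mm below the apex. Using
voxel centres and a half-open interval avoids double counting at the
boundary, and makes the ROI exactly equivariant under axis-aligned
rotations of the whole dataset (this is asserted in the tests). Volume is
`voxel count x voxel volume` — the readout a segmentation package gives —
and density is the arithmetic mean HU over the ROI. Reports round volume
to the nearest mm^3 and densities/percentages to one decimal, matching
clinical table precision; full precision is retained internally.

Note that the ROI is anchored to the apex landmark at each timepoint. A
pure height change therefore shifts the T1 ROI slightly down the axis,
which can move its volume and mean HU even when the segmentation is
unchanged: the measurements behave exactly like their clinical
counterparts, which are also re-anchored per scan.

## Surface morphology

The T1 mesh is brought into the T0 frame by rigid ICP (`register_rigid`):
point-to-surface correspondences (so the result does not depend on the
target's vertex density), least-squares update by SVD, convergence when the
RMS correspondence distance changes by less than the tolerance. **No
scaling is estimated** — a similarity transform would absorb real
remodelling into the alignment.

Two choices matter and are exposed as arguments of
`compare_condyle_studies()`:

* **Initialisation**: the landmark-derived condylar frames of the two
  timepoints are aligned first. ICP then only refines a small residual,
  which keeps it out of wrong local minima (the condyle/ramus shape is
  nearly a surface of revolution, so a cold-started ICP can converge to an
  axially rotated solution).
* **Support region** (`registration = "support"`, the default): only
  vertices more than `head_cap_mm` (20 mm) below the topmost mesh point —
  the ramus stump — drive the registration. Remodelling concentrates on the
  head; registering on the stable stump prevents, say, a uniform anterior
  apposition from being absorbed as an anterior translation. `"full"` uses
  every vertex, for meshes that do not include a stump.

Signed distances are computed per T0 vertex as the distance to the closest
point on the registered T1 surface, signed by the T0 outward vertex normal:
positive = target outward = apposition (red), negative = resorption (blue),
matching the conventional colour map (`export_colormap` writes a PLY with
the scalar channel and an 8-bit diverging blue-white-red colour channel,
clamped at a configurable ±1 mm by default).

The five anatomical surfaces are defined relative to the condylar frame: a
vertex is *superior* when its direction from the head centre is within 45
degrees of the superior axis; otherwise it takes the 90-degree azimuthal
quadrant (anterior/medial/posterior/lateral) of its direction in the
anterior-medial plane. Any fixed rule here is a convention; this one is
simple, total (every vertex gets exactly one label), equivariant under
rigid motion, and produces all five regions on any closed head mesh.
Distances are summarised over the head region only (`measure_cap_mm`, 12 mm
below the apex by default), which keeps the means clear of the head/ramus
junction.

## Cohort statistics

The Wilcoxon signed-rank test is implemented with the conventions of
common clinical statistics software: zero differences dropped, average
ranks on ties, tie-corrected variance, no continuity correction, two-sided
p from the normal approximation. With these conventions the test reproduces
the reference cohort's published p-values exactly at printed precision
(density 0.002 per side, right axis 0.02, left height 0.09). An exact
method (`method = "exact"`, n ≤ 25) enumerates the null distribution of the
positive rank sum over the observed rank multiset by the shift algorithm,
and therefore handles ties, unlike the textbook signed-rank tables.

Two details deserve a note:

* **SD divisor**: the published summary mixes conventions — the
  intercondylar SD (8.22) is a population SD (divisor n) while the density
  SD (4.45) is a sample SD (divisor n−1). `summarize_values()` therefore
  takes the divisor as an explicit argument instead of hiding a default.
* **Continuity correction**: the exact p-value of a discrete statistic and
  its uncorrected normal approximation can differ by about 0.02 at n = 20
  near mid-range p, simply because the exact p jumps in steps of the
  point probabilities. With the optional 0.5 continuity correction
  (`continuity = TRUE`, the same option `stats::wilcox.test` exposes) the
  two methods agree within 0.01 for n ≥ 20; the package's agreement checks
  use that pairing. Reporting keeps the uncorrected convention because that
  is what reproduces the published tables.

`build_cohort_report()` consumes a long table of per-condyle deltas and
emits the per-variable/side summary and test tables; rows with missing
deltas are excluded with a message, and an all-zero variable is reported as
not-computable rather than erroring the whole report.

### Reference cohort data notes

The bundled tables carry the published per-patient values exactly as
printed. `validate_reference_changes()` recomputes each density percent
change from its own pre/post cells and flags two cells that disagree with
their printed percentage (patients 1 and 7, left side). The flags are
informational: summaries intentionally use the printed percentages, which
is demonstrably what the published summary statistics were computed from.
A few published summary cells are not recoverable from the printed
per-patient data at all (the intercondylar p-value of 0.005 recomputes to
about 0.006, the right-height p of 0.18 to about 0.21, the class III
subgroup mean of 32.8 to 33.2, and the −1.02% overall height change needs
unprinted baseline heights); these are documented here and are not asserted
anywhere.

## The synthetic phantom

There is no public imaging for this workflow, so validation uses a
synthetic condyle with exact ground truth: a capsule-shaped ramus (radius
6 mm, default apex-gonion length 62 mm, axis tilted 15 degrees in the
coronal plane) topped by an ellipsoidal head (semi-axes 10 x 8 x 8 mm),
voxelised at 0.5 mm into air (−1000 HU), a 1.5 mm cortical shell (1400 HU)
and a noisy trabecular core (N(550, 50) HU). Landmarks are analytic; the
mesh is the voxel-boundary surface of the mask — sharing provenance with
the voxel data exactly as a segmentation export does — post-processed with
20 Taubin smoothing passes to remove the voxel staircase (the smoothing is
volume-preserving to well under 1%, and without it the staircase normals
bias signed-distance means low by 15–20%).

Prescribed remodelling is carried by **independent channels** so that every
parameter has exact truth: the apex landmark moves along the apex-gonion
line (height), the transverse-diameter landmarks rotate in the coronal
plane (axis inclination), the contralateral condylar centre rotates about
the foramen vertex (intercondylar angle), the head surface moves along
outward vertex normals by per-region offsets (blended over a 10-degree band
at region borders and tapered to zero over 2 mm at the head/ramus
junction), and HU inside the mask are scaled and noised (density). The
border blending attenuates recovered per-region means by a few percent of
the offset — the prescribed 0.2 mm anterior offset reads back at about
0.19 mm — which is inside the stated 0.05 mm recovery tolerance and is the
expected behaviour of any smooth region transition.

`generate_cohort()` draws per-patient remodelling from distributions that
emulate a bimaxillary-surgery cohort (height N(−0.7, 0.8) mm; axis
N(+6.9, 8.9) right / N(+1.05, 6.71) left; intercondylar N(−10.8, 8.22);
density percent N(−33.74, 4.45); surface offsets N(region means, 0.3),
truncated more than 3 SD out so extreme draws stay within the phantom's
geometric validity). Metadata follow a fixed scheme: every third patient
female, the last sixth of patients class II, the rest class III.

What the phantom does *not* emulate: real condylar anatomy (it is
deliberately schematic — ground-truth tractability beats realism for
validating measurement operators), CBCT physics (no beam hardening,
scatter or partial-volume modelling beyond the voxel grid itself), and
segmentation error (masks are exact). Passing recovery tests therefore
demonstrate the correctness of the measurement operators, not robustness
to acquisition artefacts or observer variability.

## Numerical choices and problem sizes

* Voxel spacing 0.5 mm for phantom recovery work (the generator refuses a
  spacing coarser than the cortical shell); 0.3 mm where at least 1e5
  trabecular voxels are needed; analytic-solid volume oracles at 0.25 mm
  and 0.5 mm to demonstrate better-than-halving convergence.
* ICP: up to 300 iterations at 1e-6 mm RMS-change tolerance inside the
  comparison pipeline; closest-point queries use a uniform-grid
  acceleration structure (cell size about twice the median triangle edge)
  implemented in C++.
* Degenerate inputs error early and specifically: empty masks, empty ROIs,
  apex outside the volume, zero-length projected lines, meshes without
  consistent outward normals, all-zero difference vectors.
* Determinism: every stochastic step takes a seed; the phantom restores
  the caller's RNG state, and identical inputs produce byte-identical
  report CSVs.

## Known limitations

* DICOM support is a deliberately small subset: explicit VR little endian,
  single-frame axial CT slices with identity in-plane orientation — the
  shape of typical CBCT exports. Oblique NIfTI orientations are rejected.
* PLY I/O is ASCII only; STL welding assumes exact coordinate matches
  (within 1e-6 mm), as produced by mesh exporters.
* The anatomical parcellation is a fixed geometric rule, not a
  curvature-based segmentation; region borders on real anatomy are a
  convention.
* The reference cohort prints one volume value per patient, so per-condyle
  volume statistics cannot be reproduced from it.
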