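# condylometry

Quantifies remodelling of the mandibular condyle between two CT/CBCT
timepoints — typically before and one year after bimaxillary orthognathic
surgery. The package is aimed at maxillofacial imaging researchers who need
the standard six-parameter assessment to be reproducible from code instead
of manual software workflows, and at methodologists who want a fully
synthetic, ground-truthed test bed for such pipelines.

Per condyle and timepoint it measures:

| parameter | definition |
|---|---|
| ramus height *h* | ‖apex − gonion‖ (mm) |
| intercondylar angle | ∠(A, vertex, B) at the anterior foramen magnum border, A/B = condylar centres (deg) |
| condylar axis inclination | ∠(transverse diameter line, ramus axis) after coronal projection (deg) |
| condylar volume *V* | voxel volume of the segmentation within 15 mm below the apex along the condylar axis (mm³) |
| mean bone density | mean HU over the same region |
| surface change | per-region mean signed distance d̄ (mm) between registered T0/T1 meshes; d > 0 apposition, d < 0 resorption |

Pre/post changes are reported absolutely and as percentages
(Δ% = 100·(T1 − T0)/T0); a height loss beyond 6% of the pre-surgical value
flags condylar resorption (Hoppenreijs criterion). Cohort-level analysis
uses a Wilcoxon signed-rank test per variable and side (asymptotic,
SPSS-compatible conventions, plus an exact tie-aware method), with explicit
SD-divisor control.

The package includes:

* readers/writers for NIfTI, single-frame CT DICOM series, STL, PLY (with a
  per-vertex signed-distance channel and colour map) and JSON landmarks,
  normalised to the LPS patient frame;
* rigid ICP surface registration (point-to-surface, C++ accelerated, no
  scaling) with a stable-support option for remodelling studies;
* a five-region anatomical parcellation of the condylar head;
* a bundled 12-patient (24-condyle) reference cohort with per-patient
  printed values and a report generator reproducing its summary tables;
* a synthetic condyle phantom (capsule ramus + ellipsoid head, cortical
  shell + trabecular core in HU) with exact ground truth for all six
  parameters, and a seeded cohort generator.

See the vignette (`vignettes/condylar-remodelling-workflow.Rmd`) for the
methods and every design decision.

## Worked example

Generate a phantom condyle, apply a known remodelling, and run the full
pipeline:

```r
library(condylometry)

spec <- phantom_spec(spacing_mm = 0.5, seed = 7)
ph   <- generate_phantom(spec)
rem  <- remodel_spec(height_delta_mm = -0.9, axis_rotation_deg = 5.5,
                     intercondylar_delta_deg = -12.3,
                     surface_offsets_mm = c(anterior = 0.15, posterior = -0.2),
                     density_scale = 0.68, hu_noise_sd = 20, seed = 8)
pair <- apply_remodeling(ph, rem)
compare_condyle_studies(pair$pre, pair$post)
#> <condyle_comparison> left condyle, T0 -> T1
#>   height -0.90 mm (-1.45%)
#>   intercondylar -12.30 deg, axis +5.50 deg
#>   volume +78 mm^3 (+2.90%), density -290.4 HU (-32.2%)
#>   surfaces (mean mm): anterior +0.14, posterior -0.19, medial -0.00,
#>   lateral -0.00, superior -0.00
```

Every prescribed change is recovered: the landmark channels (height, both
angles) exactly, the density scale (0.68 → −32%) within the ROI's sampling
noise, and the per-region surface offsets within the stated 0.05 mm
tolerance (border blending reads 0.15 as 0.14). The volume change reflects
the region of interest re-anchoring to the displaced apex, exactly as the
clinical measurement does.

Cohort statistics on the bundled reference data:

```r
meas <- reference_measurements()
rep  <- build_cohort_report(meas)
subset(rep$tests, variable %in% c("density_hu", "axis_deg", "height_mm"))
#>    variable  side  n    W          z           p method
#>    axis_deg  left 12 49.0  0.7844645 0.432767581 normal
#>    axis_deg right 12 68.0  2.2749472 0.022909099 normal
#>  density_hu  left 12  0.0 -3.0594117 0.002217721 normal
#>  density_hu right 12  0.0 -3.0594117 0.002217721 normal
#>   height_mm  left 12 17.5 -1.6885482 0.091306042 normal
#>   height_mm right 12 23.0 -1.2590232 0.208021966 normal
```

The bone-density decrease is significant on both sides (p = 0.002), the
right condylar axis change at p = 0.02 — the published values at printed
precision.

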