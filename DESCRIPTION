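Package: condylometry
Title: Morphovolumetric and Densitometric Quantification of Mandibular
    Condylar Remodelling from 3D Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reproducible digital workflow for quantifying remodelling of
    the mandibular condyle between two imaging timepoints (e.g. before and
    one year after orthognathic surgery). Implements six measurements on
    CT/CBCT-derived data: ramus height, intercondylar angle, condylar axis
    inclination, condylar volume and mean bone density (Hounsfield units)
    over a 15 mm region of interest, and per-region articular surface change
    from rigidly registered surface meshes (signed apposition/resorption
    distances over anterior, posterior, medial, lateral and superior
    surfaces). Includes readers and writers for NIfTI, single-frame CT DICOM
    series, STL, PLY and JSON landmark files; an SPSS-compatible Wilcoxon
    signed-rank test (asymptotic and exact); cohort summary tooling with a
    bundled 12-patient reference dataset; and a synthetic condyle phantom
    generator with exact ground truth for validating every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
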