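Package: aortascreen
Title: Automatic Abdominal Aortic Aneurysm Screening from Lumen and Thrombus Segmentations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Geometric screening pipeline for abdominal aortic aneurysm (AAA)
    detection from 3D lumen and intraluminal-thrombus label volumes. Fuses the
    masks into a whole-aorta model, extracts a refined aortic centerline via
    skeletonization and medial voxel paths, isolates the abdominal tract
    between the renal arteries and the iliac bifurcation, measures the maximum
    wall-to-wall diameter on cross-sections perpendicular to the centerline
    together with thrombus volume, and classifies each case against the 30 mm
    clinical threshold. Includes synthetic vascular phantoms with analytic
    ground truth, cohort-level screening metrics, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
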