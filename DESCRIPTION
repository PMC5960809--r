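Package: ctavg
Title: Average-Brain CT Templates and Subtraction-Based Detection of Small
    Hemorrhages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds an average-brain computed-tomography template from control
    head scans by multi-stage deformable registration (rigid, affine and
    B-spline free-form deformation driven by a stochastically sampled
    mutual-information metric with adaptive stochastic gradient descent),
    deforms the template to individual subjects, and flags small hyperdense
    lesions such as traumatic hemorrhages by voxelwise subtraction of the
    template from the subject scan. Includes NIfTI input/output and
    Hounsfield-unit preprocessing, a seeded synthetic head-phantom generator
    with ground-truth lesion records, lesion-level sensitivity scoring, and a
    command-line interface covering the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    png,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
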