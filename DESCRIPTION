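Package: maskeval
Title: Patient-Wise and Structure-Wise Evaluation of Multi-Structure
    Segmentation Masks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates automatic delineations of multi-structure targets
    (for example radiotherapy gross tumour volumes and involved lymph
    nodes) against expert ground truth. Implements the patient-wise Dice
    score and directed boundary-distance summaries (95th-percentile
    Hausdorff distance, average and median surface distance) together
    with a structure-wise framework built on the coverage fraction:
    structure-level positive predictive value and sensitivity, true and
    false structure volumes, and surface distances restricted to detected
    structures so that false-positive structures cannot contaminate them.
    Includes 3D connected-component labelling with configurable
    connectivity, a CT Hounsfield-window transform, a synthetic ellipsoid
    phantom generator for fully reproducible testing, NIfTI mask input
    and output, and per-patient and cohort reporting with a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
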