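Package: craniossm
Title: Image-Based Statistical Shape Models for Cranial Defect Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds statistical shape models directly on binary voxel
    occupancy grids of skull segmentation masks and uses them to complete
    defective skulls and design cranial implants. Provides similarity-transform
    registration of binary volumes, PCA-based shape models (mean shape,
    variation matrix via pseudo-inverse, projection and reconstruction),
    template-subtraction and SSM-based shape completion, automatic implant
    extraction by median smoothing, morphological opening and connected
    components, surface-distance evaluation metrics (Dice, border Dice, 95th
    percentile Hausdorff distance), NRRD and NIfTI mask input/output, and a
    parametric skull-phantom simulator with controlled defects for fully
    self-contained benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
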