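Package: ventjac
Title: Transformation-Based CT Ventilation Imaging with User-Defined
    Jacobian Constraints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes transformation-based CT ventilation images (Jacobian
    determinant volume-change maps) from deformable-image-registration
    displacement fields, evaluates the stability of the ventilation metric
    under single-voxel displacement perturbations via an analytic bound,
    and manufactures displacement fields whose Jacobian determinant image
    equals a user-defined target via Laplacian-regularized augmented
    Lagrangian constrained optimization.  Includes landmark-based spatial
    accuracy evaluation in millimeters, synthetic-data generators with
    closed-form ground truth, and NIfTI input/output for scalar and
    vector volumes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    RNifti,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
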