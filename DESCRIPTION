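Package: grom
Title: Geometry-Based Reduced Order Modeling for Brain Solute Transport
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps precomputed finite-element solutions of glymphatic-function
    models between subject-specific brain geometries via image-registration
    deformation fields, builds a proper-orthogonal-decomposition (POD) reduced
    basis on a target geometry, and solves two steady-state models -- a
    two-compartment tracer-transport model and a seven-network poroelastic
    (MPET) pressure model -- in the reduced space. Includes a reproducible
    synthetic cohort of annular brain-slice geometries (meshes, rasterized
    intensity images, and analytic inter-subject deformation maps) emulating a
    clinical cohort with a healthy-like majority and an iNPH-like subgroup
    with enlarged ventricles, a multi-resolution demons image registration,
    and a finite-element core with first- and second-order Lagrange elements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
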