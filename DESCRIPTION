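Package: lastrain
Title: Phasic Left Atrial Strain Analysis from 4D Gated Cardiac CT
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
                  role = c("aut", "cre"))
Description: Measures three-dimensional left atrial (LA) phasic mechanics
    from 4D (3D + time) retrospective ECG-gated cardiac CT. Computes
    per-element endocardial area strain on triangulated surface-mesh
    sequences, automatically segments the atrial cycle into reservoir,
    conduit and contractile phases, and extracts global and regional
    phasic strains and peak strain rates together with chamber
    volumetrics. Includes a baseline multi-resolution B-spline
    free-form-deformation tracker for propagating an end-diastolic mesh
    through image frames, a synthetic 4D atrial anatomy and cohort
    generator for validation, and the cohort-level statistical battery
    (pooled t-tests, exact categorical tests, mixed ANOVA, ROC with
    bootstrap confidence intervals and DeLong comparisons, and k-means
    phenotype clustering).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    car,
    cluster,
    jsonlite,
    pROC,
    RNifti,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
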