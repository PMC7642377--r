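Package: fovfat
Title: Surrogate Measures and Calibration for Abdominal Subcutaneous
    Adipose Tissue Volumetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies abdominal subcutaneous adipose tissue (ASAT) from
    labeled axial volumes. Computes the fully segmented reference ASAT
    volume together with six surrogate measures that remain computable on
    field-of-view truncated data (two single-slice fat thicknesses, two
    landmark-bounded partial areas and two partial volumes, anchored on
    the femoral heads or the anterior superior iliac spines), calibrates
    linear conversion equations from surrogate to reference volume by
    ordinary least squares, and evaluates predictive agreement via
    Pearson correlation, the standard deviation of percent differences
    and Bland-Altman limits of agreement, stratified by sex and pooled.
    Includes a synthetic phantom-cohort generator with analytic ground
    truth for validation, an FOV-truncation operator, NIfTI/JSON/CSV
    input-output, and a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'conditions.R'
    'AllClasses.R'
    'AllGenerics.R'
    'phantom.R'
    'cohort.R'
    'io.R'
    'surrogates.R'
    'calibration.R'
    'pipeline.R'
    'fovfat-package.R'
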