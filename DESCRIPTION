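Package: tibiamech
Title: Micro-CT Morphometry, Voxel-Based Micro-FE and Bending Mechanics for
    Rodent Tibia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable pipeline for the computational core of
    rodent tibial-loading studies: trabecular and cortical morphometry from
    micro-CT image volumes (BV/TV, Tb.Th, Tb.Sp, Tb.N, cross-sectional areas,
    perimeters and principal second moments of area), density-calibrated
    voxel-based micro-finite-element strain analysis under axial compression,
    and three-point-bending structural and estimated tissue-level mechanical
    properties. Ships a synthetic-phantom generator with analytic ground
    truth (annulus, plate and rod lattices, a scaled whole-tibia phantom with
    calibration inserts), a bilinear force-displacement curve generator, and
    a longitudinal group-study simulator, so every stage is testable without
    scanner data. Group comparisons use two-way repeated-measures ANOVA with
    Tukey multiple comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    EBImage,
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
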