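Package: peridose
Title: Analytical 3D Out-of-Field Photon Dose Estimation for Coplanar
    Isocentric Radiotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Closed-form three-dimensional estimation of the peripheral
    (out-of-field) photon dose delivered during coplanar isocentric
    radiotherapy, including intensity-modulated and volumetric-arc
    techniques.  Provides the piecewise analytical dose model with its
    treatment-specific correction factors (treatment efficiency, field
    area, head leakage), calibration of the three model coefficients
    against a reference 3D dose distribution by Nelder-Mead fitting,
    field-size extraction from 50% isodose areas, whole-grid dose-cube
    computation with in-field masking, organ dose-volume histograms,
    readers and writers for BEAMnrc/DOSXYZnrc .3ddose and NIfTI volumes,
    a command-line interface, and a synthetic voxel-phantom generator so
    the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
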