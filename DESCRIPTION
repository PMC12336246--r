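Package: limbdeform
Title: Soft-Tissue Deformation Under Compression Leggings: Analytical Model and Scan-Based Measurement
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts and measures soft-tissue deformation of the lower limb
    under compression leggings. Couples an analytical elasticity model
    (orthotropic fabric compliance, a Boussinesq-type pressure-stretch
    relation, the Lame thick-walled annulus stress field, a Neo-Hookean
    tissue parameterisation, and a Runge-Kutta forced damped oscillator for
    vibration loading) with an anthropometric measurement pipeline that
    slices body-scan meshes into cross-sections, extracts marker-coloured
    contours from rendered images, computes centroid-anchored radial
    profiles, and quantifies deformation as the with/without-garment radius
    difference. A synthetic-data module generates every pipeline input with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
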