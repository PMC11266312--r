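Package: svformula
Title: Validation of Stroke-Volume Prediction Formulae from Arterial Pressure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating published formulae that predict left-ventricular
    stroke volume (SV) from arterial pressure, age and anthropometry against a
    beat-to-beat reference method. Ships a registry of 22 historical SV
    formulae (Starr, Jackson, Bridwell, de Simone, Skrabal, Lu, Remington and
    derivatives), the data-integrity filters used in tilt-table heat-stress
    protocols (plausible SV range, +/- 2 SD blood-pressure screen), a
    four-metric model-selection procedure (Pearson r, Hedges g, sum of squared
    residuals, bias) with competition-rank aggregation stratified by posture
    and ambient condition, Bland-Altman limits of agreement, matched-pairs
    power analysis via the noncentral t distribution, and a seeded synthetic
    generator of study-shaped hemodynamic records for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
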