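Package: oxishift
Title: Wavelength-Shift and SpO2 Error Analysis for Pulse-Oximetry Component
    Pairing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how the finite spectral width of real LEDs and the
    non-uniform responsivity of photodetectors shift the effective molar
    extinction coefficients of oxy- and deoxyhemoglobin, and how that shift
    biases pulse-oximetry SpO2 estimates computed with the common linear
    calibration relative to the Beer-Lambert model. Provides parametric
    (Gaussian and skewed-Gaussian) and sampled spectral models, a closed-form
    product-of-Gaussians pairing analysis, effective-extinction weighting, a
    photoplethysmogram forward simulator with ratio-of-ratios extraction,
    SpO2 error profiles over the clinically critical 90-100% saturation
    window, a component registry of candidate light sources, and a small
    command-line interface for design-phase component selection.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
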