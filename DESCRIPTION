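Package: dualslope
Title: Self-Calibrating (Dual-Slope) Broadband Diffuse Reflectance
    Spectroscopy: Simulation, Extraction, Inversion and Perturbation
    Robustness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for broadband (460-1030 nm) visible/near-infrared
    diffuse reflectance spectroscopy (DRS) with a symmetric two-source,
    two-detector fiber probe.  Simulates four-channel DRS measurements
    under the photon-diffusion forward model with per-channel spectral
    transfer characteristics, exposure times, dark signal, shot noise and
    a catalog of instrumental perturbations; extracts effective
    extinction spectra by the single-slope and self-calibrating
    (dual-slope) ratio formulas; inverts extinction spectra into skin
    chromophore concentrations (blood volume fraction, hemoglobin oxygen
    saturation, water, melanin, dry matter) and Rayleigh-Mie reduced
    scattering parameters by bounded nonlinear least squares; and
    quantifies the robustness of each extraction method to instrumental
    perturbations via RMSE deviation statistics and relative parameter
    deviations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
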