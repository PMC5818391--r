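Package: nemaquant
Title: Synthetic NEMA IEC Body Phantom Imaging and Quantification
Version: 0.1.0
Authors@R:
    person("nemaquant", "developers", email = "nemaquant@example.org",
           role = c("aut", "cre"))
Description: Analytic model of the NEMA IEC body phantom (six hot spheres,
    cylindrical lung insert, warm background) together with a SPECT-like and
    PET-like image simulator (Gaussian point-spread function, calibrated
    counts or kBq/mL values, Gaussian or Poisson noise). Implements the
    standard quantification workflow used in emission-tomography phantom
    studies: fixed-fraction threshold VOIs, background-adapted threshold VOIs,
    CT-based reference ROIs, sensitivity-factor calibration, recovery
    coefficients for activity concentration and volume, threshold sweeps with
    best-threshold selection, and line profiles for detectability analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
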