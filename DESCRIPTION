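Package: surromod
Title: Surface Surrogate Motion Models for Lung Tumor Tracking
Version: 0.1.0
Authors@R:
    person("Kenneth", "Ostberg", email = "kostberg@example.org", role = c("aut", "cre"))
Description: Tools to evaluate external surface surrogates for respiratory
    lung-tumor motion modeling. Extracts four surrogate signals (abdominal
    point height, thoracic point height, radial distance mean, and a
    surface-derived volume) from laser-line torso point-cloud sequences,
    removes slow baseline drift with a running median over exhalation
    extrema, fits a linear amplitude-plus-derivative (hysteresis) motion
    model to sparse cine-CT-like tumor observations, and benchmarks it
    against 4DCT-style phase binning. Includes a synthetic-data generator
    emulating irregular breathing, deforming torso surfaces, hysteretic
    tumor trajectories and quasi-random cine sampling, plus experiment
    drivers for surrogate comparison and training-set-size sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
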