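Package: mmwr
Title: Magnetic Microwire Rheometry of Airway Mucus Gels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of live-cell magnetic microwire rheometry (MMWR)
    experiments on mucus gels secreted by air-liquid-interface airway
    epithelial cultures. Converts microwire displacement under a calibrated
    step magnetic force into creep compliance, fits the four-parameter
    Burgers viscoelastic model to extract steady-state compliance and
    zero-shear viscosity, classifies gels as viscoelastic liquid or solid
    from creep recovery, and runs per-donor cohort comparisons with ratio
    paired t tests. Includes the drag model for a cylinder translating
    parallel to a no-slip surface, wire-height estimation from multi-channel
    intensity z-profiles, sub-pixel wire tracking from image stacks, and a
    synthetic-data generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff,
    yaml,
    withr,
    deSolve
Config/testthat/edition: 3
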