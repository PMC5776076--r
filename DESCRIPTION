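Package: tkrwear
Title: Cross-Shear and Contact-Stress Dependent Wear Simulation for Total Knee Replacements
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A pre-clinical wear-simulation framework for the polyethylene
    bearing of total knee replacements. Implements a modified Archard wear
    law whose non-dimensional wear coefficient depends on the frictional-work
    cross-shear ratio and the non-dimensional contact stress, an elastic
    foundation (Winkler) contact stage with periodic worn-surface update, a
    multidirectional pin-on-plate simulator that generates the wear-law
    inputs, nonlinear fitting of the wear-coefficient surface, and inverse
    calibration-curve procedures for compressive elastic properties.
    Synthetic parametric implant geometry is generated in-package so that no
    proprietary implant CAD is required.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
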