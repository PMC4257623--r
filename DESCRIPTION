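Package: stillframe
Title: Geometric Modelling of Still-Shot Diffraction Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models serial-crystallography still shots recorded without
    goniometer rotation. Computes the signed minimal rotation angle that
    brings each reciprocal-lattice point onto the Ewald sphere, refines
    crystal orientation and unit cell by damped Gauss-Newton minimisation
    of a positional or hybrid (positional plus angular-offset) target,
    estimates effective mosaicity and mosaic block size from the angular
    residuals by binned least squares or a smoothed top-hat maximum
    likelihood, predicts the observable Bragg spot set under the fitted
    envelope, and scores predictions in equal-volume resolution shells.
    Includes a seeded synthetic still-shot simulator so that every
    estimator can be validated by parameter recovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
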