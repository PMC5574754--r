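Package: qfasajoint
Title: Joint Estimation of Diet Composition and Calibration Coefficients
    from Fatty Acid Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative fatty acid signature analysis (QFASA) with
    simultaneous estimation of predator diet proportions and fatty acid
    calibration coefficients from predator and prey signature samples
    alone.  Provides the constrained least-squares estimator minimizing the
    summed Aitchison distance between observed and modelled predator
    signatures, the classical estimator conditioned on externally supplied
    calibration coefficients, compositional preprocessing (zero
    replacement, signature augmentation), estimability diagnostics, and
    simulation tools (regular diet grids, random calibration coefficients,
    synthetic prey libraries, noise-free predator signatures) for
    validation with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
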