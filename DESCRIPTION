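Package: nmrlbp
Title: Geographic-Origin Classification of 1H NMR Spectra with
    Rotation-Invariant Uniform Local Binary Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies the geographic origin of plant material from 1H NMR
    spectra by rendering each spectrum as a fixed-size grayscale image,
    extracting rotation-invariant uniform local binary pattern (riu2 LBP)
    histogram features, and classifying with k-nearest neighbours, decision
    trees, or a linear support vector machine under stratified five-fold
    cross-validation. Includes a synthetic two-class NMR spectrum simulator
    with a sugar-region class effect, solvent-region exclusion preprocessing,
    a deterministic spectrum rasterizer, confusion-matrix metrics, k-means
    cluster visualization, and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
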