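Package: gaborpop
Title: Gabor Population Model of V1 Responses to Uncomfortable and Natural Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the population response of primary visual cortex (V1) to
    sine gratings, spectrally shaped noise and natural-image surrogates, using a
    bank of Gabor model neurons whose spatial-frequency, orientation and phase
    tunings follow physiologically inspired distributions. Stimuli are generated
    internally (gratings, 1/f noise with a raised radial cosine spectral peak,
    and 1/f^beta Gaussian surrogates for natural scenes), optionally prefiltered
    by a contrast sensitivity function, and scored by the total magnitude and
    excess kurtosis of the population response. The package reproduces the
    finding that midrange-spatial-frequency ("uncomfortable") stimuli evoke
    larger, less sparse population responses than natural images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    png,
    Rcpp,
    stats,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
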