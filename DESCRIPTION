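Package: ramancaps
Title: Growth-Duration Classification of Rice Grains from Raman Spectra
    with Capsule Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end chemometrics pipeline that classifies japonica
    rice grains into accumulated-temperature-zone growth-duration classes
    from their Raman spectra. Spectra are smoothed with zero-phase
    Butterworth filtering, baselines are removed by a filter-difference
    scheme, and seven characteristic starch/sugar crest windows are folded
    into 28x28 pseudo-images. A capsule network with dynamic
    (agreement) routing is trained on the images with a margin loss.
    Includes a seeded synthetic-spectrum generator so the whole pipeline
    can be exercised and validated without instrument data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    tools,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
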