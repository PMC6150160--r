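Package: topiQuant
Title: Release Kinetics, Skin Permeation and Quantitative
    Immunohistochemistry for Topical Drug-Delivery Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis toolkit for topical drug-delivery
    experiments. Fits the four classical drug-release laws (zero-order,
    first-order, Higuchi and Korsmeyer-Peppas) to dissolution profiles and
    selects the best model by determination coefficient; estimates
    steady-state flux and the permeability coefficient from cumulative
    membrane-permeation series; quantifies DAB chromogen in brightfield
    immunohistochemistry images by H-DAB colour deconvolution, zoned
    pixel-intensity scoring and an energy-per-pixel measure with control
    subtraction; and compares treatment groups with pairwise Welch t-tests.
    Includes seeded generators for synthetic dissolution curves, permeation
    series, H-DAB images of known composition and group measurement sets, so
    the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
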