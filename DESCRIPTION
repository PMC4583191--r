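Package: ruvclean
Title: Removal of Unwanted Variation for Gene Co-Expression Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cleans systematic (unwanted) variation from log-scale gene
    expression matrices before gene-gene correlation estimation, using the
    RUV-random approach: factors of unwanted variation are estimated from
    negative-control genes by singular value decomposition and removed by
    ridge regression. Includes a seeded simulation framework with known
    gene-gene correlation structure, accuracy metrics on the Fisher z scale
    (a squared-error norm and the wrong-sign percentage), standard
    normalization comparators (quantile normalization, per-sample background
    offset removal), plot-ready diagnostics (correlation densities, p-value
    histograms, relative log expression summaries, principal component
    projections), negative-control discovery, and guilt-by-association
    candidate gene prioritization.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    limma
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
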