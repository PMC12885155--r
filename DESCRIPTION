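Package: guttmap
Title: Guttman Error Maps and Loevinger Scalability Coefficients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes pairwise Guttman-error ratios and Loevinger scalability
    coefficients (h_ij, h_i, H) for dichotomous or polytomous multi-item
    scales, with support for complex-survey sampling weights via an integer
    rescaling transform and case expansion, and renders the banded
    traffic-light Guttman error map as a symmetric annotated heatmap with
    optional smoothing. Includes a synthetic-data module for scalogram
    generation, dataset emulation by resampling, and weighted fixtures, plus
    a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ggplot2,
    rlang,
    grid,
    grDevices,
    stats,
    utils,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
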