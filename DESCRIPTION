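Package: warpscreen
Title: Dynamic Time Warping Screens for Omics Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Screens large sets of biological time courses ("entities") for
    significant dynamic-time-warping (DTW) alignment to a small set of
    reference time courses ("endpoints"), or to the same entities measured in
    a second experiment on a possibly different time grid.  Significance is
    estimated by permuting the temporal order of both series and applying
    Benjamini-Hochberg false discovery rate control.  Includes a pre-filter
    for significant time courses, a Pearson-correlation comparison arm, a
    synthetic shift-and-noise benchmark generator with ground-truth scoring,
    diagnostic plots, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
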