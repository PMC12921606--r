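Package: spheroidquant
Title: Quantification of Spheroid Growth and Invasion from 2D Fluorescence Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Semiautomatic quantification of growth and matrix invasion of
    fluorescently labeled 3D spheroids from 2D time-series images. Computes a
    spheroid-core mask by minimum cross-entropy thresholding in two modes
    (compact spheroids thresholded per timepoint; disintegrating spheroids with
    a fixed-area mask re-placed on the brightest pixels), detects invading
    cells outside the mask as extended intensity maxima with a prominence
    criterion expressed as a fraction of the image intensity range, excludes
    oversized artifacts by disk containment, and reports per-object geometry
    (area, perimeter, circularity, roundness, solidity, distance to the mask
    boundary) together with per-image summaries. Includes a synthetic-image
    generator with planted ground truth and a command-line driver.
License: MIT
Encoding: UTF-8
Imports:
    EBImage,
    Rcpp,
    grDevices,
    png,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
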