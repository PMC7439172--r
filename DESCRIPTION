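Package: otsu2d
Title: Robust Two-Dimensional Otsu Thresholding with Energy-Based Image Partitioning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Global image thresholding by the two-dimensional Otsu criterion, made
    robust to salt-and-pepper noise and to vertically uneven illumination. The
    joint histogram of each pixel's gray level and its neighbourhood-smoothed
    gray level is built from median and median-average filtered images, the
    optimal threshold pair maximises the trace of the between-class scatter
    matrix, and unevenly lit images are first cut into two evenly lit parts
    along a maximum-energy splitting line found by dynamic programming. Two
    partition-based thresholding schemes (independent per-part thresholds, and
    a single pair maximising the product of the per-part criteria) are fitted
    by otsu2d(). Includes misclassification-error and Dice evaluation against
    ground-truth masks and a seeded synthetic-scene generator for blob-like
    foregrounds under impulse noise and illumination gradients.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: png, tiff, stats, graphics, grDevices
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
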