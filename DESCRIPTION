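Package: cementr
Title: Semi-Automated Counting of Dental Cementum Growth Increments in
    Tomographic Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cementochronology on greyscale tomographic image
    stacks of tooth roots: straightening of the circumferential cementum
    band along a user-supplied midline spline, steerable directional
    Gaussian filtering to enhance increment contrast, signal-to-noise and
    contrast-to-noise image-quality metrics, and a statistics-driven
    semi-automated algorithm that counts circum-annual increment pairs as
    peak-trough systems of smoothed luminance along random radial
    transects.  Includes a synthetic sine-wave and banded-phantom
    validation harness for assessing counting accuracy and robustness
    under controlled noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
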