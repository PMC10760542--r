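Package: punctascan
Title: Quantification of Fluorescent Puncta Along Neurites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detection and measurement of fluorescent puncta along a
    user-drawn neurite path in calibrated micrographs, as used for
    GLR-1::GFP accumulation in the C. elegans ventral nerve cord.
    Extracts a calibrated linescan from a maximum-intensity projection,
    detects puncta by Gaussian smoothing, Phansalkar local adaptive
    thresholding and minimum-size filtering, and measures peak-to-bead
    intensity, full width at half maximum, and density per 10 microns
    per animal. Includes group statistics (Shapiro-Wilk normality gate,
    two-sample Kolmogorov-Smirnov test, wild-type normalization) and a
    synthetic-data generator with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
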