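Package: cytotexture
Title: Texture-Based Screening of Oral Cytology Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An image-analysis pipeline for screening exfoliative oral
    cytology (PAP-stained smear) images for dysplastic change. Provides
    contrast enhancement and region-of-interest cropping, fuzzy c-means
    intensity segmentation of cells from background, gray-level
    co-occurrence matrix (GLCM) texture features (entropy, contrast,
    energy, correlation, homogeneity), subject-level two-group statistics,
    a ratio-based composite scoring index thresholded at 1 for
    normal-versus-malignant calls, and ROC evaluation. A calibrated
    synthetic cytology image generator with ground-truth masks makes the
    whole pipeline testable end to end without clinical images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    e1071,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
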