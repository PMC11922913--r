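Package: rdnet
Title: Residual Depth-Wise Networks and Multi-Fusion Contrast Enhancement for Mammogram Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benign/malignant mammogram classification built around a
    compact residual depth-wise convolutional network trained entirely in R.
    Implements the multi-fusion contrast-enhancement operators used to prepare
    mammograms (histogram equalization, contrast-limited adaptive histogram
    equalization, intensity inversion, and Gaussian high-boost sharpening),
    a seeded preprocessing and stratified train/validation/test protocol,
    confusion-matrix evaluation metrics, and a deterministic generator of
    synthetic breast phantoms with benign (smooth) and malignant (spiculated)
    lesion morphology so the whole pipeline can be exercised without access
    to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
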