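Package: lungtexture
Title: Windowed Texture Quantification and Classification for
    Edge-Enhanced Lung Projection Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the fine speckle texture visible in high-magnification,
    propagation-based X-ray phase-contrast projection images of small-animal
    lungs, and uses it to classify image regions.  The pipeline standardizes
    image intensities by percentile clipping and exact histogram specification,
    derives four feature modes (identity, local-Otsu skeleton, gradient
    magnitude, Gaussian-blurred Laplacian), summarizes each over a lattice of
    overlapping square windows together with a bandpass spectral power sum and
    directional-filter orientation statistics, and feeds the resulting eleven
    predictors per window to random-forest classifiers evaluated by
    leave-one-mouse-out cross-validation for lung segmentation and ventilation
    pressure calling.  A seeded synthetic phantom generator reproduces the
    statistical structure the analysis assumes (pressure-dependent speckle,
    multiplicative rib bands, a blurred heart, a cranial-caudal orientation
    gradient) so every stage is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    randomForest,
    jsonlite,
    tiff,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
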