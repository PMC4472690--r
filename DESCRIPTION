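Package: mhimotion
Title: Video-Based Body-Movement Quantification with Motion History Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates a per-frame index of general body movement from video
    using frame differencing, binary thresholding and a timestamp-decay motion
    history image, and provides the downstream toolchain used to validate such
    estimates against contact sensors: burn-in removal, z-score outlier
    cleaning, absolute differencing, multi-axis Euclidean norms, pressure-grid
    reduction, equal-width windowing, and normalized lagged cross-correlation
    with best-positive-lag selection and one-sample effect-size summaries.
    Includes a seeded generator of synthetic videos and co-registered sensor
    streams sharing a latent movement profile, a minimal uncompressed-AVI
    reader and writer, and a batch command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    png,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
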