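Package: capedema
Title: Quantitative Assessment of Pericapillary Edema from Capillaroscopy and Confocal Microscopy Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying pericapillary edema in nailfold video
    capillaroscopy (NVC) and reflectance confocal laser scanning microscopy
    (CLSM) images. Implements a difference-of-Gaussians image sharpness score
    for detecting the "foggy" appearance caused by epidermal water
    accumulation, a vessel-size estimator based on Gaussian smoothing with a
    relative intensity threshold, and a gain-invariant dermal-papilla
    brightness ratio. Includes a synthetic phantom generator (blurred hairpin
    capillaries, concentric papilla cross-sections, before/after effect pairs,
    sharpness time courses) for end-to-end validation, smoothing-spline time
    course fitting, and nonparametric group comparison (Kruskal-Wallis with
    Bonferroni-corrected pairwise follow-up and box-plot summaries). Results
    are returned as tidy tibbles and plot with ggplot2.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    png,
    tiff,
    stats,
    utils,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
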