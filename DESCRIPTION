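Package: stainr
Title: Detection and Correction of Spatial Artefacts on Microarray Probe Grids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects probe-level spatial artefacts (stains) on Affymetrix-style
    microarray intensity grids using fold-change and residual based probe noise
    scores, optionally smoothed over a distance-weighted 2D window, and corrects
    or filters the affected probes before summarization. Includes quantile and
    loess normalization helpers, an RNA-fraction linear model for metabolic
    labeling controls, RMA-style median-polish probeset summarization, text CEL
    reading/writing, a spike-in simulator that plants random or realistically
    shaped artefacts with known ground truth, and precision-recall evaluation of
    detection accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    limma,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    EBImage,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
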