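Package: oligosort
Title: Spike Sorting for Oligofiber Nerve Recordings with Subtraction-Based
    Overlap Resolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sorts extracellular spikes recorded from few-fiber ("oligofiber")
    sympathetic nerve preparations on a single electrode. Detects spikes against
    a robust median-based noise floor, extracts six waveform features, groups
    spikes by k-means clustering (cityblock or squared-Euclidean) with silhouette
    diagnostics, verifies within-cluster homogeneity by principal-component
    Hotelling T-squared distances, and recovers overlapped spikes from synchronous
    discharge with a data-based subtraction algorithm that matches waveform
    residuals back against the original recording. Putative single-fiber units
    are validated by refractory-period analysis, multimodal Gaussian fitting of
    log interspike-interval distributions with corrected-AIC model selection, and
    preceding-interval dependence of waveform features. Includes a ground-truth
    synthetic-recording generator for end-to-end accuracy benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    cluster,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
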