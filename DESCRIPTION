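Package: spikefuzz
Title: Automatic Spike Sorting with SVD Features and Fuzzy C-Means
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detection, sorting and online classification of extracellular
    action potentials. Spikes are detected with a median-based automatic
    threshold and quadratic sub-sample peak fitting, aligned by cubic-spline
    upsampling into 24-sample waveforms, reduced by row-centered singular
    value decomposition with scree-test (optimal coordinates) selection of
    the number of components, and sorted by unsupervised fuzzy C-means with
    the number of clusters estimated from the histogram of per-spike l1-norms.
    Cluster quality is reported through fuzzy validity indices (partition
    coefficient, partition entropy, proportion exponent) and the L-ratio
    isolation measure, whose threshold drives a drift alarm during streaming
    classification against a persisted sorter prototype. A seeded synthetic
    benchmark generator and a ground-truth evaluation harness make the whole
    pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    e1071,
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
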