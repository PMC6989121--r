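Package: minisync
Title: Synchrony, Behavior and Stimulus-Response Analysis for Dual-Region
    Miniscope Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for dual-region head-mounted miniscope
    calcium-imaging sessions with synchronized accelerometer and
    optogenetic-stimulation logs. Detects calcium-event onsets at sub-frame
    resolution with a matched filter, computes the population Epanechnikov
    kernel sum and its mean+2*sigma synchronous events, builds the
    co-firing synchronous-pair (SP) graph with region-scope labels and an
    arc-diagram layout, classifies SP-triggered behavioral acceleration,
    segments rearing and turning epochs from IMU channels, and classifies
    optogenetic stimulus responses (mean+2*sigma responders, sigmoid-fit
    onset latencies, paired-t three-way modulation). A fully deterministic
    synthetic session generator provides ground truth for every stage.
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
    igraph,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
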