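Package: cdktrace
Title: Single-Cell Analysis of Dual CDK4/6 and CDK2 Kinase Translocation Reporter Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing simultaneous CDK4/6 and CDK2 kinase
    translocation reporter (KTR) time series from live-cell imaging of
    cycling and quiescence-released epithelial cells. Provides a corrected
    CDK4/6 activity that removes the additive CDK2 cross-contribution from
    the CDK4/6 reporter (with a regression estimator of the contamination
    fraction from CDK4/6-inhibition experiments), threshold-with-persistence
    detection of CDK4/6-on, CDK2-on and APC/C-off landmarks, classification
    of cell fates at quiescence release, mitotic exit and after acute
    stress, population statistics (event-aligned medians with bootstrap
    intervals, cumulative activation curves, stress dose-response by CDK2
    level, phase-plane trajectories, live-fixed Rb phosphorylation
    matching), and a seeded synthetic cohort generator with ground-truth
    labels that emulates the kinetic structure of the imaging data.
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
    mclust,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
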