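Package: edrclass
Title: Cardiorespiratory Classification of Voluntary and Involuntary
    Electrodermal Reactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects electrodermal reactions (EDRs) in skin conductance
    recordings and classifies each reaction as voluntarily or involuntarily
    generated using simultaneously recorded respiration and blood volume
    pulse.  Detection uses a first-difference threshold rule on one-second
    windows of the EDA trace; respiration-induced reactions are screened with
    a respiration length line filter against robust trimmed-statistic
    thresholds; the remaining reactions are classified by testing the
    heart-rate/respiration cross-correlation of a short segment around the
    reaction against bootstrap prediction bands fitted to resting data.  A
    seeded synthetic signal generator emulating the resting coupling
    (respiratory sinus arrhythmia) and its transient lapse before voluntary
    reactions makes the full pipeline testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
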