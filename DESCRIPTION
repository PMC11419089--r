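Package: hemigait
Title: Bilateral Spinal Locomotor Circuit Model of Tied-Belt and
    Split-Belt Locomotion After Lateral Hemisection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a bilateral spinal rhythm-generating circuit for cat
    hindlimb locomotion: two persistent-sodium half-center rhythm generators
    coupled by commissural interneuron pathways, driven by supraspinal
    inputs and by belt-speed-dependent sensory feedback under presynaptic
    inhibition. Reproduces speed-sweep predictions for cycle, stance and
    swing durations in intact, hemisected and transected states during
    tied-belt and split-belt treadmill protocols, extracts step-cycle phase
    durations and duty factors from simulated activity, generates synthetic
    repeated-measures cat datasets, and compares simulation and data with a
    two-factor (state x speed) repeated-measures ANOVA and a qualitative
    sign-agreement report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
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
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
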