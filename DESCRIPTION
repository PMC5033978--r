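Package: clampdecay
Title: Simulation and Decay-Rate Analysis of Motor Memories in Error-Clamp Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the trial-by-trial decay of motor memories
    measured with error-clamp (channel) trials after force-field adaptation.
    Builds alternating force-field/error-clamp trial schedules, simulates
    reaching cohorts with a two-state trial-to-trial learner (at full 1 kHz
    trajectory fidelity or a fast metric-level tier), extracts the standard
    kinematic and force readouts (movement time, directional error, force at
    peak velocity), and estimates and compares exponential decay rates across
    visual-feedback conditions with an exhaustive subsampling bootstrap and a
    permutation test on the fitted parameters.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    minpack.lm,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
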