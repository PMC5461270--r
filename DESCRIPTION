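Package: sidestepr
Title: Switching Mobility Control for Bipedal Sidestep Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates a minimal three-mass model of bipedal sidestepping in
    the frontal plane, controlled by a switching mobility scheme in which
    three autonomous actuators (two legs and one inter-leg actuator) allocate
    a global velocity command among themselves from their instantaneous
    mobility and discrete role-switching rules for propulsion, balancing, and
    leg swing. Provides the fixed-step simulator with a compiled inner loop,
    a direction-change trial protocol with timing and parameter-sensitivity
    sweeps, gait-event analytics (touchdowns, step intervals, peak foot
    heights), reaching-time statistics, deterministic configuration and
    result serialization, and plotting helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    patchwork,
    generics,
    yaml,
    jsonlite,
    arrow,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
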