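Package: valueramp
Title: Spike-Train Analysis of Tonic Dopamine Activity Tracking Gradual
    Reward-Value Changes
Version: 0.1.0
Authors@R:
    person("Value-Ramp", "Maintainers", email = "maintainers@valueramp.dev",
           role = c("aut", "cre"))
Description: Tools for analysing single-unit spike trains recorded during a
    Pavlovian task in which the cued reward value ramps up, ramps down, or
    stays fixed within a trial. Implements Gaussian-kernel spike density
    functions with stop-time truncation, baseline firing-rate estimation,
    binned firing-rate regressions against time and reward value,
    interspike-interval based burst/non-burst classification, a
    neuron-resampling bootstrap comparing firing modes, logistic fits of
    choice behaviour, and a fully seeded synthetic-data generator
    (inhomogeneous renewal spike trains, gaze traces, lick events, choice
    sessions) so every stage of the pipeline can be validated against ground
    truth without recorded data. A command-line entry point orchestrates
    generate, analyze and report stages reproducibly.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
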