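Package: vaquetics
Title: Heart-Rate-Derived Energetics for Vaquejada Simulation Tests
Version: 0.1.0
Authors@R: person("VST", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for 1 Hz heart-rate/GPS telemetry from
    vaquejada simulation tests (VST) in horses: reading and validating
    exercise sessions, gait segmentation by speed thresholds, race
    detection, heart-rate-derived energy expenditure, cost of transport
    and metabolic power, blood-lactate curve summaries, and pull-horse
    versus helper-horse group statistics. Includes a seeded synthetic
    cohort generator so every stage is testable without raw device
    exports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
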