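Package: thermoshuttle
Title: Annotation and Analysis of Shuttling Ectotherm Temperature Traces
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing near-continuous skin-temperature traces of
    shuttling ectotherms recorded with miniature bio-loggers. Labels
    thermoregulating versus non-thermoregulating sections of a trace,
    detects upper and lower set-points with a hysteresis state machine,
    counts shuttles, classifies animals as thermoregulators, and computes
    seven thermoregulation parameters together with the accuracy of
    thermoregulation index (db). Includes additive bio-logger calibration
    against cloacal readings, a seedable Newtonian heat-exchange simulator
    that generates synthetic shuttling traces and treatment cohorts, and
    cohort-level descriptive summaries with seedable permutation tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
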