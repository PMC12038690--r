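Package: pegsim
Title: Simulation and Differential Signal Analysis for Paper-Based
    Electrochemical Gas Sensor Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic simulation of paper-based electrical gas sensors
    (PEGS) for breath-ammonia monitoring, together with the differential
    signal-processing chain used to turn raw multi-channel conductance
    recordings into ammonia readouts.  Models the ionic conductance of
    acid-, base- and untreated sensors, humidity-driven water-film
    dynamics, acid-base neutralization by NH3 and CO2 uptake; builds
    chamber and simulated-breathing exposure protocols; extracts
    concentration-proportional slopes from smoothed, normalized,
    differential traces; fits calibration curves with limit-of-detection
    estimation; and generates synthetic breath cohorts for paired
    statistical analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
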