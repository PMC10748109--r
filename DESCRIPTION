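Package: smartsensr
Title: Smart-Sensor Monitoring and Consensus Alerting for Bioreactor
    Cell-Expansion Runs
Version: 0.1.0
Authors@R:
    person("Process Analytics", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: A monitoring toolkit for multichannel bioreactor batch-run time
    series from automated cell-expansion (e.g. CAR-T manufacturing) platforms.
    Implements six complementary smart sensors over eight hard-sensor channels
    (temperature, dissolved oxygen, pH, gas flow, glucose, lactate, exhaust O2
    and CO2): a statistical signal-disturbance indicator for simultaneous
    non-biological glucose/lactate drops, Bollinger-band proximity monitors
    for glucose and lactate, weighted-weighted-average (WWA) aggregators over
    the setpoint and non-setpoint sensor groups, and a fuzzy-membership
    stability controller on the glucose setpoint distance. Binary alert
    streams are fused by consensus voting (three or more simultaneous alerts)
    into merged events, with coincidence tables and summary percentages per
    sensor and per run. A seeded synthetic batch-run generator with injectable
    disturbances (sensor-line bubbles, channel dropout, mid-run shutdown)
    stands in for proprietary platform data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
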