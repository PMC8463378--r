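Package: stroketriage
Title: Transport-Paradigm Catchment Modelling for Acute Stroke Under
    Diurnal Traffic
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models prehospital triage of suspected large-vessel-occlusion
    stroke between three transport paradigms (mothership, drip-and-ship,
    drip-and-drive) with a conditional-probability good-outcome model,
    paradigm-specific onset-to-needle and onset-to-groin timelines, and
    hourly directional traffic deltas relative to a 3 a.m. baseline.
    Classifies every cell of a planar region grid by the paradigm with the
    highest predicted probability of good outcome, summarises catchment
    areas per hour and day type, generates synthetic regions and hospital
    networks for fully reproducible experiments, and summarises
    emergency-operation logs by hour and day type.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
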