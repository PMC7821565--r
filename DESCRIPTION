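Package: fnirsconn
Title: Prefrontal fNIRS Functional Connectivity Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for two-wavelength functional near-infrared
    spectroscopy (fNIRS) recordings of the prefrontal cortex during sustained
    attention and decision-making tasks. Converts raw optical intensities to
    oxy-/deoxy-hemoglobin concentration changes via the modified Beer-Lambert
    law, suppresses motion artifacts with correlation-based signal improvement
    (CBSI), segments recordings into event-defined task periods, estimates
    per-period partial-correlation networks over a 15-channel montage,
    thresholds them into binary graphs, and summarizes them with connection
    density and local clustering. Includes group-level connection-frequency
    maps, regression of behavioral outcomes on network metrics, and a
    synthetic-data generator with known connectivity ground truth for
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    signal,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
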