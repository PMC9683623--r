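Package: heatrisk
Title: Annual Heat Exposure Indices and Heat Stress Illness Rate Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying annual-scale associations between outdoor heat and
    heat stress illness (HSI) morbidity. Derives hourly thermal indices (relative
    humidity, the National Weather Service heat index, and outdoor wet-bulb globe
    temperature via the Liljegren energy-balance method) from basic meteorology;
    aggregates them into a catalogue of thirty annual exposure indices (absolute and
    anomaly-based, full-year and heat-season); fits negative-binomial rate models
    with installation fixed effects and population offsets; constructs block-bootstrap
    rate-ratio confidence intervals (basic, percentile, and BCa); and projects future
    case burden under warming scenarios. A synthetic-data module generates hourly
    weather and installation-year outcome panels with known ground truth so every
    pipeline stage is testable without restricted health or bulk meteorological data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    data.table,
    stats,
    utils,
    yaml,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
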