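Package: thermotrace
Title: Torpor, Thermoregulation and Neural-Activity Time-Series Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for physiological time series from studies of
    mouse thermoregulation and fasting-induced torpor: torpor-bout scoring
    from core-temperature telemetry, heat-loss index and indirect-calorimetry
    derivations, a fiber-photometry delta-F/F pipeline (isosbestic reference
    correction, rolling-percentile baselining, calcium-transient metrics),
    Q10-based thermosensitivity classification of neurons, EEG relative band
    power, and beat-interval heart-rate summaries. Includes seeded synthetic
    generators with ground truth for every stage so the whole pipeline is
    testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
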