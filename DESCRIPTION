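Package: acousticOccu
Title: Dynamic Occupancy Models from Automated Acoustic Detections with
    False Positives
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and maximum-likelihood estimation toolkit for
    multi-season (dynamic) wildlife occupancy models built from automated
    acoustic monitoring data. Simulates latent occupancy dynamics
    (initial occupancy, colonization, extinction), Poisson call production
    and soundscape false alarms, beta-distributed classifier scores, and
    probability-based aggregation of event-level detections into
    three-state encounter histories (no detection / uncertain automated
    detection / certain manually verified detection). Fits the
    multiple-detection-states dynamic occupancy model that accommodates
    false positives by maximum likelihood, and provides a scenario-grid
    driver for measuring estimator bias over replicated simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
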