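Package: emabandit
Title: Contextual Multi-Armed Bandits for Predicting Ecological Momentary Assessments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A stream-learning framework that predicts a mobile-health user's
    next vector of ecological momentary assessment (EMA) answers by letting a
    contextual multi-armed bandit choose, at every time step, among a global,
    an entity-centric, and a k-nearest-neighbourhood incremental regressor.
    Includes UCB1, Thompson, random, optimal and worst sampling strategies,
    four bandit configurations (contextual/simple x whole-vector/ensemble),
    a prequential (predict-then-learn) evaluation harness with warm-start
    support, and a synthetic EMA cohort generator with per-user baselines,
    AR(1) temporal structure, correlated items and missingness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
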