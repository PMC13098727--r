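Package: twinforge
Title: Offline Digital Twins for Two-Wave Cohort Risk Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds offline, simulation-capable digital twins from two-wave
    longitudinal cohort data. Provides a reproducible synthetic cohort
    generator with known ground-truth risk structure, ontology-grounded
    retrieval and a contract-based language-model relevance agent for
    semantic feature selection (with Lasso and mutual-information
    baselines and a semantic audit), leakage-safe cross-validated risk
    prediction with class rebalancing and calibration metrics, coarse
    low/medium/high risk-state construction by exact one-dimensional
    k-means with frozen baseline centroids, two-stage state-transition
    and outcome models, and a deterministic counterfactual "what-if"
    scenario engine with placebo, monotonicity, and cross-K stability
    protocols, all coordinated by a deterministic orchestrator with
    critic checks and content-addressed run manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    glmnet,
    ranger,
    xgboost,
    nnet
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
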