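Package: firehawkdr
Title: Fire Hawk Optimization and a Desk-Scale Diabetic Retinopathy
    Screening Pipeline
Version: 0.1.0
Authors@R:
    person("firehawkdr", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Implements the Fire Hawk Optimizer (FHO), a population-based
    metaheuristic in which the best-ranked candidate solutions act as
    "fire hawks" whose territories partition the remaining "prey"
    candidates, together with an improved variant (IFHO) that scales the
    hawk step by an adaptive exploration-exploitation factor
    f(a) = a + (1 - a) * exp(-g * t). Around the optimizer the package
    provides the supporting components of a desk-scale diabetic
    retinopathy screening pipeline: classical benchmark objectives with
    seeded shifts, fuzzy-logic (Wang-Mendel style) salt-and-pepper
    denoising, SMOTE class balancing on flattened images, hyperparameter
    tuning of a small neural classifier by validation accuracy,
    confusion-matrix metrics with AUC, stratified k-fold
    cross-validation, a labeled synthetic fundus image generator, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
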