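Package: icresp
Title: Receptive-Field and Sound-Level Analysis for Paired-Condition
    Auditory Midbrain Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis chain for single-unit auditory electrophysiology in
    which each neuron serves as its own control across control, deactivated
    and recovery conditions. Extracts frequency response area (FRA) metrics
    (spontaneous-rate criterion masks, per-frequency excitatory thresholds,
    polynomial frequency tuning curves, characteristic frequency, threshold,
    response area, total spikes), classifies rate-level functions (RLFs),
    computes half-maximum sound levels and an ROC-based Discriminability
    Index, and runs the nonparametric population battery (Kolmogorov-Smirnov,
    Friedman, Wilcoxon with Sidak correction, Spearman, exact Fisher r x 2,
    bootstrap median confidence intervals). A seeded synthetic-population
    generator with Poisson trial noise and an analytic ground-truth ledger
    makes every stage testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'data-io.R'
    'synthetic.R'
    'fra-analysis.R'
    'rlf-analysis.R'
    'population-stats.R'
    'pipeline.R'
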