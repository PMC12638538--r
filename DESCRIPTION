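Package: crossmu
Title: Cross-Limb Motor Unit Analysis of Acute Unilateral Resistance Exercise
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for bilateral pre/post motor-unit studies
    of acute unilateral resistance exercise. Simulates a bilateral pre/post
    cohort (motoneuron-pool spike trains, force traces, intramuscular motor
    unit potential templates), extracts the standard neuromuscular metrics
    (maximal voluntary contraction, force steadiness, phase-specific firing
    rates, inter-spike-interval variability, recruitment thresholds,
    cumulative spike train, motor unit potential area/turns/negative-peak
    ratio, near-fibre jiggle), and fits the leg-by-time hierarchical mixed
    models with estimated marginal means, Cohen's d effect sizes and
    marginal/conditional R-squared.
License: MIT
Encoding: UTF-8
Imports:
    signal,
    lme4,
    lmerTest,
    emmeans,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
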