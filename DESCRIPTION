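Package: gazerisk
Title: Gaze-Conditioned Evidence-Accumulation Models of Risky Choice
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Process models of binary risky choice constrained by eye
    fixations. Implements within-alternative (one-layer, two-layer and
    hybrid leaky accumulators) and within-attribute (normalized and
    categorical difference) accumulation dynamics with attentional
    modulation, leak and mid-range default substitution; static benchmark
    models (expected value, expected utility, cumulative prospect theory,
    gaze-regression variants and choice heuristics); two-step maximum
    likelihood fitting of choices and decision times under fixed or
    collapsing decision boundaries; model comparison by AIC, prediction
    accuracy and cross-validation; parameter-recovery harnesses;
    descriptive analyses of choices and eye movements; and a seeded
    synthetic-experiment generator that emulates a 5x5 amount-by-
    probability lottery design with Markov fixation sequences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
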