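Package: rrchoice
Title: Resource-Rational Strategy Selection for Risky Choice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models risky choice between monetary gambles as resource-rational
    selection from a toolbox of cognitive heuristics. Implements eleven classic
    choice strategies (minimax, maximax, least-likely, most-likely,
    better-than-average, equal-weight, tallying, probable, lexicographic,
    priority heuristic, weighted-additive) as decision procedures that emit
    elementary-information-process traces, quantifies each strategy's expected
    payoff and cognitive cost by simulation, and selects strategies by a
    payoff-minus-weighted-cost rule executed with a trembling-hand error.
    Provides per-participant grid-search fitting, posterior-predictive checks,
    a six-parameter cumulative prospect theory baseline, synthetic
    choice-problem and agent-population generators, and parameter-recovery
    scoring, so the full analysis pipeline runs on simulated data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
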