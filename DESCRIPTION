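Package: larvarc
Title: Reverse Correlation of Larval Run-Turn Navigation Under Optogenetic
    White-Noise Stimulation
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for behavioural neural coding experiments in
    Drosophila larvae: event-triggered stimulus averages (reverse correlation)
    of run-to-turn and turn-to-run transitions under Bernoulli optogenetic
    flicker, binned step-response transition probabilities with a binomial
    z-test and its normal-approximation validity rule, calcium-imaging
    delta-F/F quantification with water-only baseline testing, and two-choice
    preference-index statistics. Includes an agent-based simulator of larval
    populations with known stimulus filters (a linear-nonlinear hazard model
    of the run/turn switch), synthetic calcium traces and synthetic two-choice
    counts, so every stage is validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
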