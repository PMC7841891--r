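Package: afibcea
Title: Markov Cohort Cost-Effectiveness Model for Stroke Prevention in
    Atrial Fibrillation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Decision-analytic Markov cohort model comparing warfarin,
    rivaroxaban and dabigatran (110 mg / 150 mg) for stroke prevention in
    non-valvular atrial fibrillation. Provides the cycle-kernel engine
    (four health states, five competing clinical events, annual cycles
    with discounting), an individual-level microsimulation cross-check,
    incremental cost-effectiveness analysis with strict and extended
    dominance, net monetary benefit and willingness-to-pay decision
    rules, one-way (tornado) sensitivity analysis, and probabilistic
    sensitivity analysis with beta/log-normal parameter distributions,
    cost-effectiveness acceptability curves and incremental
    cost-effectiveness plane ellipses. All base-case inputs ship as a
    plain-text configuration fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
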