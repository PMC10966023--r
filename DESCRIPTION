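Package: lpicea
Title: Cost-Effectiveness of Prophylactic Laser Peripheral Iridotomy for
    Primary Angle-Closure Suspects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A two-arm Markov cohort model comparing prophylactic laser
    peripheral iridotomy (LPI) against observation for primary angle-closure
    suspect (PACS) from the Japanese healthcare payer's perspective. The
    package houses the full parameter set (annual transition probabilities,
    state utilities and state costs with age brackets), runs the yearly-cycle
    cohort engine with first-year tunnel states, computes incremental
    cost-effectiveness ratios and net monetary benefit, and performs scenario
    sweeps over entry age and horizon, one-way deterministic sensitivity
    analysis with tornado ranking, and probabilistic sensitivity analysis
    with method-of-moments beta/gamma sampling and cost-effectiveness
    acceptability curves. An individual-level microsimulation of the same
    state-transition process serves as a brute-force validation oracle for
    the cohort engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
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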