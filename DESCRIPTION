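Package: biopsycea
Title: Cost-Effectiveness Analysis of Transperineal Versus Transrectal
    Prostate Biopsy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Daily-cycle tunnel-state Markov cohort model comparing
    transperineal and transrectal prostate-biopsy strategies from a health
    care payer perspective over a two-week horizon. Provides deterministic
    base-case evaluation (costs, quality-adjusted life years, incremental
    cost-effectiveness), one-way threshold sensitivity analysis by bisection,
    probabilistic sensitivity analysis with beta/gamma parameter
    distributions and cost-effectiveness acceptability curves, three
    scenario analyses, and an individual-level microsimulation that serves
    as a brute-force validation oracle for the cohort engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
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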