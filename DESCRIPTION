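Package: lonelycea
Title: Cost-Effectiveness Modelling of Loneliness Alleviation in Older People
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A decision-analytic Markov cohort model of a community service
    that connects lonely older people to social activities, evaluated against
    no intervention over five annual cycles. Implements the four-state cohort
    engine (not lonely, moderately lonely, severely lonely, dead) with an
    engagement/dropout process, accrual of discounted loneliness-free years
    and of loneliness-linked health and social care costs, incremental
    cost-effectiveness analysis with dominance handling, one-way (tornado)
    sensitivity analysis, and probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves. Ships the published parameter
    table as its default configuration and supports user parameter sets via
    JSON, YAML and CSV.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    parallel,
    jsonlite,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
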