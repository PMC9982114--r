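Package: haus
Title: Health Appraisal for Urban Systems
Version: 1.0.0
Authors@R: person("HAUS", "Maintainers", email = "maintainers@haus.example.org",
    role = c("aut", "cre"))
Description: Quantifies and monetizes the health impacts of changes to urban
    environments using the impact-pathway approach. Odds-ratio-adjusted
    attributable mortality and morbidity, statistical life-years lost (YLL)
    and years lived with illness (YLD), lag-adjusted project-lifetime totals,
    and societal unit-cost valuation (VSL/VSLY, cost of illness) with bearer
    and cost-component disaggregation. Includes an impact-pathway registry
    with threshold activation, age-structured population handling, scenario
    comparison reporting, a Monte-Carlo oracle for the closed-form risk
    arithmetic, a synthetic fixture generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
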