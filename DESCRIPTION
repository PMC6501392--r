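Package: fait
Title: Impact Assessment for Translational Health Research
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Mixed-methods research impact assessment for translational
    health projects, combining a Payback-style domains-of-benefit
    scorecard, a cohort-level cardiovascular health-economic model that
    converts blood-pressure reductions into events, deaths and
    disability-adjusted life years averted, a social-return-on-investment
    (SROI) engine with conservative and base-case scenarios, programme
    logic model and case-narrative components with a data-readiness audit,
    and a seeded synthetic two-arm screening-cohort generator so the whole
    pipeline can be exercised and tested at desk scale.
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
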