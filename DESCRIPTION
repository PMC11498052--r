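Package: hivdid
Title: Staggered Difference-in-Differences Evaluation of Medicaid
    Expansion Effects on HIV Care Continuum Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quasi-experimental evaluation of staggered state
    Medicaid expansion on HIV care continuum outcomes. Derives annual
    person-year indicators (retention in care, antiretroviral therapy
    receipt, viral suppression, CD4 at enrollment) from person-level care
    records; estimates group-time average treatment effects on the
    treated with not-yet-treated comparison states, event-study and
    overall aggregation with size-proportional weights, clustered
    multiplier-bootstrap inference and a pre-trends test; and provides
    alternative estimators (comparative interrupted time series via
    estimating equations, propensity-score-weighted
    difference-in-differences, ridge-augmented synthetic control on
    state-level summaries) plus sensitivity analyses. Includes a
    synthetic cohort generator with configurable injected effects for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    sandwich,
    splines,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
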