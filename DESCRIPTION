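Package: twophaseprev
Title: Two-Phase Prevalence Estimation for Adolescent Psychiatric Epidemiology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating lifetime prevalence of mental health
    disorders from two-phase epidemiological designs in which a
    high-sensitivity screen (phase 1) selects participants for structured
    diagnostic interviews (phase 2). Implements attrition-adjusted
    prevalence estimators (including a sub-cohort imputation term for
    instruments whose screens were administered asymmetrically across
    school cohorts), sexual-orientation and gender-discontent group
    construction from attraction and gender-contentment items, relative
    risks with chi-square significance coding, table rendering, and a
    seeded synthetic-cohort generator that mirrors the sampling design so
    the full pipeline can be validated by simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    readr,
    tibble,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
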