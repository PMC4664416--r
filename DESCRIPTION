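Package: prevcast
Title: Chronic-Disease Prevalence Projection from Registry Prevalence and
    Mortality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for projecting the future burden of a chronic disease from
    routinely collected registry data. Back-calculates age- and sex-specific
    incidence from observed prevalence and mortality via the discrete-time
    illness-death recurrence, projects prevalence and case counts forward
    under configurable incidence and excess-mortality scenarios using
    cohort-component demographic bookkeeping, decomposes a projected case
    increase into population-size, age-structure and relative-survival
    drivers by counterfactual substitution, and solves for the annual
    incidence decline that keeps prevalence flat. Includes a synthetic-country
    generator with known ground truth and an individual-level microsimulation
    oracle for validating the deterministic recurrence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
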