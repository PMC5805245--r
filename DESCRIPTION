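Package: nutridyn
Title: Nutritional-Stage Dynamics of a Population by Age and Socioeconomic Status
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A population-level stock-and-flow (system dynamics) model of body
    mass index (BMI) category dynamics: an aging chain of 5-year age groups,
    each split into not-overweight, overweight and obese stocks, with births,
    deaths and annual transference rates (TRs) between adjacent BMI
    categories. Includes a heuristic that estimates the TRs per age group
    (and socioeconomic stratum) from two cross-sectional survey waves five
    years apart by constrained least squares on the fifth power of a
    column-stochastic one-year transition matrix; an obesity prevalence-ratio
    statistic comparing socioeconomic strata; a policy-scenario engine with
    timed TR overrides; a synthetic-survey generator; and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    lhs,
    minpack.lm,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    Matrix,
    jsonlite
Config/testthat/edition: 3
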