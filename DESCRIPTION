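Package: tdrp
Title: Time-Dependent Rate Phenomenon Analysis for Viral Evolutionary Rates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the time-dependent rate phenomenon (TDRP) in
    viral molecular evolution: power-law rate-decay regression of substitution
    rate estimates against their measurement timescales, constrained resampling
    of rate catalogs into phylogenetically independent pseudoreplicates, pooled
    parameter distributions with highest-posterior-density summaries and
    Fisher-combined p-values, a nonhomogeneous-Poisson simulator for assessing
    sensitivity to erroneous short-term rate estimates, and a calibrated
    rate-decay clock that converts substitution-unit phylogenies into
    calendar-time node ages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    MASS,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    multcomp
Config/testthat/edition: 3
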