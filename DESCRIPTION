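Package: wavemetrics
Title: Presence-Only Macroinvertebrate Bioassessment Metrics for Volunteer
    Stream Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Implements the presence-only benthic macroinvertebrate
    bioassessment approach used by New York State's WAVE (Water Assessments
    by Volunteer Evaluators) citizen-science program. Indicator taxa are
    selected from labelled training samples by contrasting occurrence
    frequencies between condition categories and screening per-taxon
    contributions to within-category Sorensen similarity; new samples are
    scored with the presence-of-threshold-indicator-taxa (PTIT) count metric
    and with a three-class naive Bayes posterior probability of impairment
    (TPI). Includes the packaged indicator registry with class-conditional
    occurrence frequencies, threshold-sweep evaluation of matching and
    type-1-error percentages, TPI-based site ranking, and a seeded synthetic
    community generator with exact Poisson-binomial oracles for validating
    the metrics under the class-conditional independence model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
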