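Package: aggdir
Title: Direction of Female Aggression Along Dominance Hierarchies
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the direction of aggression along female
    dominance hierarchies in group-living primates. Infers daily dominance
    ranks from submission events (decided avoidance, displacement) by
    sequential Elo-rating, standardizes scores within group and day, assigns
    each aggressive interaction a score equal to the recipient's minus the
    aggressor's standardized Elo-score, classifies daily female reproductive
    states (cycling, pregnancy trimesters, lactation) from longitudinal
    demography, and models how group composition and reproductive state shift
    aggression up or down the hierarchy with a mixed-effects model with
    crossed random intercepts. Includes Type-II Wald tests, single-step
    (Tukey-type) multiple comparisons, generalized variance-inflation
    diagnostics, simulation-based residual checks, and a synthetic
    behavioural-event generator for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmmTMB,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    car,
    multcomp,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
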