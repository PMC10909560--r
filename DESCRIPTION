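Package: migtraj
Title: Longitudinal Migration Area Classification by Group-Based
    Multi-Trajectory Mixture Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds longitudinal, migration-specific classifications of small
    areas from census-style count tables. Provides the six standard migration
    indicators (internal and international in-mover shares, in-mover age and
    tenure composition), areal-weighting conversion of counts between boundary
    systems, a group-based multi-trajectory mixture model fitted by
    expectation-maximisation with per-group polynomial mean trajectories over
    multiple census years, the usual latent-class enumeration diagnostics
    (BIC, AIC, normalised entropy, average posterior probability of
    assignment, odds of correct classification, assignment mismatch),
    classify-analyse cluster profiling with one-way ANOVA, and comparison of
    categorical area classifications via chi-square tests of independence and
    Cramer's V. A seeded synthetic-panel generator with known latent group
    structure supports parameter-recovery studies.
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
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
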