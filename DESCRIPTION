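Package: gxetools
Title: Split-Plot, AMMI and GGE Biplot Analysis of Multi-Environment
    Enzyme-Activity Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Treats enzyme and antioxidant activities measured across a
    gradient of environments (for example, water temperatures during
    natural winter cooling of fish cages) as a genotype-by-environment
    problem.  Provides split-plot analysis of variance with separate
    main-plot and sub-plot error strata, the additive main effects and
    multiplicative interaction (AMMI) model with Gollob degrees of
    freedom and per-axis F-tests, and GGE biplot analysis with the four
    interpretive views (environment relationships, which-won-where,
    mean versus stability, and ideal-entry concentric circles).  A
    synthetic-data generator with controllable effect sizes, low-rank
    interaction and two error strata supports calibration and
    parameter-recovery studies, and a validation harness replays
    published ANOVA tables from their sums of squares and degrees of
    freedom alone.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
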