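Package: twinsocial
Title: Twin Models for Social Factors and Wellbeing
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for genetically informed analysis of social phenotypes in
    classical twin designs. Implements multivariate Cholesky decomposition of
    additive-genetic (A), shared-environmental (C) and non-shared
    environmental (E) trait (co)variance with full-information maximum
    likelihood over incomplete pairs, AIC model comparison, standardized
    variance components and genetic/environmental correlations; co-twin
    control analysis via random-intercept mixed models with within-pair /
    between-pair effect decomposition; psychometric scale scoring with
    reliability (Cronbach's alpha) and age/sex residualization; and a
    synthetic twin-cohort generator with known ground truth for validating
    every estimator without access to registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse,
    withr
Config/testthat/edition: 3
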