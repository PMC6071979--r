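Package: allocluster
Title: Consequences of Ignoring Clustered Data Structure in Biomass
    Allometric Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify the consequences of ignoring clustered
    (stand-nested) sampling designs when fitting log-log biomass
    allometric models. Fits ordinary least squares and random-intercept
    multilevel models (restricted maximum likelihood, profiled over the
    variance ratio), computes the intraclass correlation coefficient,
    the design effect and the implied underestimation of standard errors
    and overestimation of t-scores, evaluates Durbin-Watson bounds tests
    for detecting clustering-induced autocorrelation, and runs
    Monte-Carlo validation studies (observed versus theoretical
    underestimation curves, ICC-versus-d regression, type-I-error
    inflation) on synthetic clustered tree-biomass data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4,
    lmtest,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
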