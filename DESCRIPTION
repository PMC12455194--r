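Package: deltalcs
Title: Latent Change Score Models for Thalamus-Hippocampus Volume Coupling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying longitudinal coupling between regional brain
    volumes with bivariate, multivariate (age-adjusted) and multigroup latent
    change score (LCS) structural equation models, estimated by normal-theory
    maximum likelihood and full-information maximum likelihood for incomplete
    follow-up. Includes a calibrated synthetic-cohort generator emulating an
    aging-cohort design (cross-sectional thalamus-cognition sample and a
    longitudinal two-scan subsample), a one-factor cognitive composite built
    from digit-symbol substitution and trail-making scores, a multivariable
    regression suite with collinearity and false-discovery-rate screening,
    selection-bias sensitivity machinery (propensity-score caliper matching,
    predictive-mean-matching multiple imputation with Rubin pooling), and
    Bland-Altman agreement summaries for paired segmentation pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
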