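Package: aucmix
Title: Predictor Correlation, Case-Mix and the Discrimination of Risk Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Seedable simulation and evaluation pipeline for studying how the
    correlation between two Gaussian predictors shapes the discrimination
    (area under the ROC curve) of two-predictor logistic risk models, both in
    the population a model is developed in and in external validation
    populations with a different case-mix. Populations are synthesized either
    from total-population predictor distributions with fixed adjusted odds
    ratios and an intercept calibrated to a target prevalence, or from
    case/control-conditional predictor distributions. Includes rank-based
    (Mann-Whitney) AUC with optional direction auto-orientation, the standard
    deviation of the linear predictor as a case-mix heterogeneity metric,
    outcome-stratified predictor summaries, closed-form Gaussian-mixture
    moments and unadjusted odds ratios, cross-population validation matrices,
    and correlation-sweep experiments tracing AUC against the correlation
    coefficient.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
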