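Package: ipascore
Title: Index of Prediction Accuracy for Binary, Survival and Competing-Risks Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Validation of risk prediction models with the index of prediction
    accuracy (IPA), a rescaling of the Brier score against the Brier score of a
    covariate-free null model. Supports binary outcomes, right-censored survival
    outcomes and competing risks with a common interpretation: 100% is a perfect
    model, 0 is a useless model and negative values flag harmful models. Provides
    the nonparametric estimators the measure needs (Kaplan-Meier, reverse
    Kaplan-Meier censoring weights, Aalen-Johansen cumulative incidence),
    inverse-probability-of-censoring-weighted Brier scores, binary AUC,
    calibration curves, IPA-versus-horizon curves, drop-one-variable IPA-gain
    tables, cause-specific Cox absolute-risk prediction via the Benichou-Gail
    product-limit formula, and a simulation toolkit for studying how IPA reacts
    to discrimination and miscalibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
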