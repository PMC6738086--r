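Package: prosash
Title: Personalised Survival Prediction for Sorafenib-Treated Advanced
    Hepatocellular Carcinoma
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements the PROSASH prognostic model for overall survival of
    patients with advanced hepatocellular carcinoma receiving sorafenib:
    evaluation of the published linear predictor, restricted-cubic-spline
    baseline survival on the log-cumulative-hazard scale, four-group risk
    stratification and individual survival curves.  Also provides the
    flexible parametric (Royston-Parmar) survival fitting machinery the model
    was built with - maximum-likelihood estimation with spline
    degrees-of-freedom selection, backward covariate selection,
    time-dependent-effect testing and Martingale-residual diagnostics -
    together with discrimination measures (Harrell's c-index,
    Royston-Sauerbrei D and R2_D), Kaplan-Meier risk-group calibration
    tables, and a synthetic trial-like cohort generator so the whole pipeline
    is testable without the proprietary trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    flexsurv,
    optparse
Config/testthat/edition: 3
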