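Package: markovcea
Title: Bayesian Multi-State Cost-Effectiveness Models with Structural
    Model Averaging
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits discrete-time multi-state (Markov cohort) models for
    hospitalization and survival by multinomial logistic regression with
    Bayesian MCMC, propagates full joint parameter uncertainty into lifetime
    discounted costs and quality-adjusted life years (one-stage probabilistic
    sensitivity analysis), and quantifies structural uncertainty across
    candidate model variants.  Predictive adequacy is measured by the
    conditional-predictive-ordinate / pseudo-marginal-likelihood (harmonic-mean
    estimator) and the deviance information criterion; Bayesian-bootstrap model
    selection probabilities turn these into model-averaging weights and mixture
    posteriors for incremental cost, QALYs, net benefit and cost-effectiveness
    acceptability.  Includes a synthetic-cohort generator with known ground
    truth, CSV/JSON persistence for every artifact, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
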