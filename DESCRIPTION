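Package: predacc
Title: Bayesian Predictive Accuracy Assessment via Leave-One-Out Coverage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Assesses the predictive capability of a Bayesian model from the
    proportion of observations covered by their leave-one-out predictive
    credible intervals. Provides the coverage-based accuracy measure
    Delta = kappa - gamma, the Full Bayesian Significance Test (FBST)
    e-value for the hypothesis kappa = gamma under a Beta posterior,
    calibrated critical values for |Delta| with a large-sample
    approximation, conjugate Exponential-Gamma and Poisson-Gamma
    predictive distributions, Bayesian exponential regression fitted by
    adaptive random-walk Metropolis, a generic leave-one-out engine, and
    a simulation study of the coverage proportion's sampling behaviour.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
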