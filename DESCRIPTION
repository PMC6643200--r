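Package: heiusual
Title: Usual-Intake Diet Quality Analysis with HEI-2010 Scoring and
    Measurement-Error Correction for Repeated 24-Hour Recalls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating population diet quality from short-term
    dietary instruments. Scores intake profiles on the 12 components of the
    Healthy Eating Index 2010; fits a multivariate two-part measurement-error
    model (nonlinear mixed model on Box-Cox/log transformed amounts with a
    probit consumption submodel for episodically consumed foods) to pairs of
    24-hour recalls; draws Monte Carlo usual-intake pseudo-populations and
    computes survey-weighted, age/sex-standardized component means and
    percent-at-maximum; estimates standard errors by a Rao-Wu stratified PSU
    bootstrap; and runs survey-weighted linear regression with forced-variable
    backward selection to examine correlates of diet quality. Includes a
    synthetic-cohort generator with known ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
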