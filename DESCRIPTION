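Package: dmpath
Title: Progressive Multistate Modelling of Diabetes Complications from
    EHR Panel Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the progression of long-term diabetes
    complications from electronic-health-record style tables.  Builds an
    incident-complication cohort through a configurable
    inclusion/exclusion cascade, classifies diagnosis codes into
    microvascular and macrovascular complication categories (including a
    biological chronic-kidney-disease rule), imputes baseline covariates
    by chained equations and carries follow-up values forward, and fits a
    five-state progressive continuous-time Markov multistate model (DM,
    microvascular, macrovascular, both, death) to panel-observed states
    with exact death times, state-level censoring and
    proportional-intensity covariate effects.  Includes a synthetic EHR
    cohort generator with known ground truth, per-transition covariate
    screening by Wald tests and AIC, likelihood-ratio tests,
    transition-probability prediction with parametric-bootstrap
    intervals, and observed-versus-expected prevalence diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    Matrix,
    MASS,
    nnet,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
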