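Package: bmigrowth
Title: Longitudinal BMI Growth-Curve Models for Genetic Association Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling childhood body mass index (BMI) trajectories
    and testing genetic effects on their level and shape. Implements four
    longitudinal growth-curve models fitted by maximum likelihood: a polynomial
    linear mixed model with continuous-time AR(1) residual correlation, a
    skew-t linear mixed model estimated by an EM algorithm, a semi-parametric
    mixed model on a cubic truncated-power spline basis, and the SITAR
    size/tempo/velocity nonlinear mixed model on a shared natural cubic
    spline. Includes obesity-risk-allele-score construction, sex-stratified
    SNP-by-trajectory association via global likelihood-ratio tests, per-age
    genetic effect curves, cluster-bootstrap model comparison, and a synthetic
    cohort generator emulating an eight-wave pregnancy cohort with adiposity
    rebound, irregular visit schedules and Hardy-Weinberg genotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    splines,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    nlme,
    withr,
    jsonlite
Config/testthat/edition: 3
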