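Package: rjds
Title: Hierarchical Bayesian Models for Double-Observer Line-Transect Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits hierarchical models for multiple-observer line-transect
    distance sampling data. Observer detections follow a bivariate probit
    with a distance-dependent correlation anchored at zero on the transect
    line (point independence); individual covariates (distance, group size,
    species, exposure) follow parametric population models including
    zero-truncated and overdispersed Poisson families; group abundance per
    cell is Poisson with lognormal overdispersion driven by habitat
    covariates. Never-detected groups are sampled by reversible-jump MCMC
    data augmentation with per-transect pseudo-groups. Includes posterior
    prediction of group and individual abundance in sampled and unsampled
    cells, detection-function diagnostics, convergence diagnostics, a
    synthetic survey simulator with a known-truth golf-tee-style fixture,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils, graphics, grDevices, yaml, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
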