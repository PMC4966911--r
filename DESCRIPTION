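Package: headbem
Title: Boundary-Element Forward Models of MEG and EEG with Cerebrospinal Fluid
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Surface-based boundary-element (BEM) forward solver for MEG and EEG
    in piecewise-homogeneous head models. Supports four-compartment
    (brain/CSF/skull/scalp, optionally non-nested) and three-shell conductor
    models with linear collocation or linear Galerkin weighting, deflation and
    the isolated source approach; dipole sources, electrode and magnetometer
    sensor models; the Geselowitz equation for the volume-current magnetic
    field; analytic layered-sphere and spherical-conductor oracles for
    verification; and relative-error/correlation machinery for skull
    conductivity sweeps, selection of optimal and equivalent skull resistivity
    ratios, and expected-error studies that quantify how omitting the CSF can
    be compensated by lowering the skull conductivity of a three-shell model.
    All experiments run on built-in synthetic sphere and perturbed-sphere
    geometry; no anatomical data are required.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    yaml,
    pracma
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
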