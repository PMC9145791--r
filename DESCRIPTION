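Package: neutkpd
Title: Semi-Mechanistic K-PD Modelling of Chemotherapy-Induced Neutropenia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for modelling absolute neutrophil count (ANC) dynamics
    during combination chemotherapy when drug concentrations are unavailable.
    Implements a transit-compartment myelosuppression model with negative
    feedback driven by kinetic-pharmacodynamic (K-PD) virtual drug
    compartments, a constant-multiplier G-CSF rescue submodel, and a
    sex/diabetes covariate model on drug potency. Provides forward simulation
    of individual ANC trajectories under body-surface-area based dosing with
    toxicity-triggered dose reduction and G-CSF rescue, generation of sparse
    synthetic cohorts, population parameter estimation by a Laplace
    approximation to the marginal likelihood, AIC-based structural model
    comparison, stepwise covariate modelling, nonparametric bootstrap,
    individual Bayesian (MAP/MCMC) prediction from sparse observations, and
    posterior-predictive assessment of grade-4 neutropenia risk.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
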