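Package: ctxlds
Title: Context-Dependent Linear Dynamical Systems for Neural Population Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers mechanisms of context-dependent computation from
    trial-averaged neural population responses. Fits constrained discrete-time
    linear dynamical system (LDS) model classes, in which the recurrent
    dynamics and/or the sensory input subspaces may differ across task
    contexts, jointly to condition-averaged population tensors by gradient
    descent, and compares them against a low-rank tensor factor regression
    (TFR) that strictly generalizes the LDS. Includes leave-one-condition-out
    cross-validation for dimensionality selection, a synthetic-task generator
    with known ground-truth dynamics, and a post-fit characterization suite:
    eigenmode spectra, decay time constants and rotation frequencies,
    non-normality (Henrici index), input loads onto left eigenvectors,
    impulse responses, observability Gramians, condition-dependent versus
    condition-independent decompositions, and simulated state and input
    perturbation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
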