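Package: jointddm
Title: Hierarchical Bayesian Drift-Diffusion Modelling with Joint EEG and
    Questionnaire Links
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for model-based analysis of two-choice motion-discrimination
    behaviour in developmental samples. Implements exact numerics for the
    two-boundary Wiener diffusion process (first-passage densities, defective
    cumulative distribution functions, deadline censoring via the survivor
    function), a hierarchical Bayesian group-difference model with truncated
    normal priors, differential-evolution Markov chain Monte Carlo sampling
    with chain migration, Savage-Dickey Bayes factors, and joint bivariate
    models linking drift-rate to a response-locked EEG slope measure and to
    ADHD symptom scores. An EEG pipeline derives the slope measure from
    continuous recordings through Reliable Components Analysis, response-locked
    epoching, and ridge-regularised linear deconvolution of overlapping
    stimulus- and response-locked activity. A synthetic-data generator produces
    behaviour, EEG and questionnaire data with known ground truth for
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
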