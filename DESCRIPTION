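Package: llvrnai
Title: Logistic Lotka-Volterra Modelling of siRNA-Induced Apoptosis Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits a predator-prey ordinary differential equation model to
    cell-viability time courses in which the living-cell population is the
    prey and the (unobservable) apoptotic strength of a transfected siRNA
    is the predator. The prey equation carries a logistic carrying-capacity
    term; the predator does not. Parameters are estimated by maximising the
    reciprocal of the summed squared relative error with a real-coded
    genetic algorithm using unimodal normal distribution crossover (UNDX)
    and minimal generation gap (MGG) selection, the hidden siRNA-strength
    profile is reconstructed by fixed-step fourth-order Runge-Kutta
    integration, and per-siRNA effect summaries (accumulated population
    difference, area under the strength curve, peak strength) are derived
    for correlation, principal-component and strong/weak classification
    analyses, including a sequence-free 'phenotypic score' of siRNA
    effectiveness. A synthetic-data generator emulating the
    ATP-luminescence assay design supports recovery studies end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
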