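Package: affbias
Title: Test-Retest Reliability Analysis of Computationally Characterised
    Affective Bias Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis pipeline for the test-retest
    reliability of two behavioural affective-bias tasks: an orthogonalized
    go/no-go task modelled with a Pavlovian-bias reinforcement-learning
    family, and an ambiguous-midpoint interpretation task modelled with
    drift-diffusion models (the EZ closed form and a 4-parameter Wiener
    likelihood).  Provides seeded task-schedule generators, generative agent
    simulators with configurable cross-session parameter correlations,
    hierarchical Bayesian model fitting by adaptive MCMC, two-stage
    reliability statistics (Pearson correlations and two-way intraclass
    correlations with confidence intervals), cross-session
    posterior-predictive transfer tests, and joint two-session models with
    the between-session correlation matrix estimated inside the model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
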