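Package: staircasesim
Title: Design, Power and Simulation of Basic Staircase Cluster-Randomised Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for basic staircase cluster-randomised trial designs, the
    incomplete stepped wedge layout in which each sequence contributes one
    control period followed by one intervention period. Provides closed-form
    variance and power calculations for the generalised least squares
    treatment-effect estimator under exchangeable and block-exchangeable
    intracluster correlation structures, a generator of individual-level
    repeated cross-sectional trial datasets, restricted maximum likelihood
    (REML) fitting of the corresponding linear mixed models exploiting
    balanced-design sufficient statistics, Satterthwaite and Kenward-Roger
    small-sample corrections, and a factorial simulation-study engine that
    computes bias, Type I error, power and confidence-interval coverage with
    Monte Carlo standard errors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), lme4, lmerTest, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
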