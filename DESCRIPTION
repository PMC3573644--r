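Package: combodose
Title: Escalation Strategies and Operating Characteristics for Two-Agent
    Phase I Dose-Finding Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design-evaluation toolkit for Bayesian adaptive dose-escalation
    in two-agent (drug combination) Phase I trials. Implements a six-parameter
    odds-type dose-toxicity model and a three-parameter copula-type extension
    of the continual reassessment method, posterior computation by prior
    importance sampling (with an adaptive Metropolis backend), next-dose
    selection by posterior-mean targeting or tolerance-restricted Bayesian
    D-optimality, three admissible-set escalation strategies (orthogonal
    neighbours, diagonal moves, previously experimented combinations),
    selection of dose combinations recommended for Phase II, and a simulation
    engine that summarises operating characteristics (experimentation and
    recommendation percentages by toxicity band, proportion of true maximum
    tolerated doses identified, per-patient mean toxicity).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
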