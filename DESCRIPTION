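Package: crdincentives
Title: Evolutionary Dynamics of Collective-Risk Dilemmas with
    Institutional Reward and Punishment
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Finite-population evolutionary dynamics of the N-player
    collective-risk dilemma, a threshold public goods game in which
    groups that fail to gather M cooperators lose their remaining
    endowment with probability r.  Strategies spread by pairwise Fermi
    imitation with exploration, giving a birth-death Markov chain over
    the number of cooperators.  The package computes expected payoffs
    under hypergeometric group sampling, the gradient of selection, the
    exact stationary distribution, group achievement, and the effect of
    institutional incentives: a fixed per-group budget split between
    rewarding cooperators and sanctioning defectors.  It derives the
    optimal state-dependent switch from pure reward to pure punishment
    that minimises the defector's fitness advantage, and includes an
    agent-based simulator of the social-learning process plus sweep
    drivers over risk, budget, switching point and incentive
    efficiencies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
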