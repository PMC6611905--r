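Package: crimedyn
Title: Evolutionary Game Dynamics of Organised Crime and Lone-Wolf Offending
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the evolutionary dynamics of a three-role
    adversarial game between honest citizens, members of a criminal (or
    terrorist) organisation, and unaffiliated lone-wolf offenders. Provides
    exact group-level acting- and investigation-stage payoffs, mean-field
    payoffs under multivariate hypergeometric group sampling, replicator
    dynamics on the population simplex, a finite-population Markov chain
    whose stationary distribution maps regimes of crime dominance,
    coexistence and eradication, an agent-based Monte Carlo simulator with
    Fermi imitation dynamics, analytic two-type invasion thresholds, and
    parameter-sweep phase-diagram utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
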