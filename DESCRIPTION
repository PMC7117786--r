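Package: zdgames
Title: Linear-Algebraic Analysis of Zero-Determinant Strategies in Repeated Games
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing zero-determinant (ZD) strategies in N-player,
    multi-action repeated games with public monitoring. Represents games,
    memory-one strategies and their Press-Dyson matrices; detects ZD strategies
    by exact rational linear algebra (subspace intersection with the span of
    the payoff matrix); extracts and solves the linear payoff relations they
    enforce; checks consistency (Rouche-Capelli) and independence of sets of
    ZD strategies; searches for ZD existence in a given game by linear
    programming; and verifies claims against stationary distributions of the
    induced Markov chain, exactly on reducible chains and by Monte-Carlo
    simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
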