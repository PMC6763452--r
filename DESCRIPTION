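Package: pdcoev
Title: Coevolution of Strategy and Learning Ability in the Spatial
    Prisoner's Dilemma
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Monte Carlo simulator for the weak prisoner's dilemma on a
    periodic square lattice in which each player's learning ability (the
    prefactor of its Fermi strategy-adoption probability) coevolves with
    its strategy under a winner-weaken-loser-strengthen rule, applied to
    both strategies, to cooperators only, or to defectors only.  Provides
    lattice initializers (uniform random and four-bar block
    configurations), a compiled asynchronous update engine, observables
    (cooperation density, stationary averaging, extinction-threshold
    scans, enduring/expanding period decomposition, per-strategy
    learning-ability statistics, snapshot export) and a command-line
    front end for reproducible experiment orchestration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
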