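Package: qpdnet
Title: Coupled Classical and Quantum Prisoner's Dilemma Games on Scale-Free Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte Carlo co-evolution of the classical prisoner's dilemma (PD)
    on one Barabasi-Albert scale-free network coupled, through a utility
    function with coupling factor alpha, to a simplified three-strategy
    quantum prisoner's dilemma (QPD) on a second network. Provides the PD and
    entanglement-dependent QPD payoff matrices with pairwise subgame
    decomposition and Nash/ESS analytics, scale-free topology generation with
    random one-to-one inter-layer matching, an asynchronous Fermi-rule
    imitation engine with independent per-layer random streams, stationary and
    ensemble observables, exact one-step transition enumeration and replicator
    dynamics baselines, and deterministic parameter sweeps reproducing the
    published phase diagrams.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
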