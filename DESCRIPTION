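Package: snncsp
Title: Stochastic Spiking Neural Network Solvers for Constraint Satisfaction Problems
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Compiles binary constraint satisfaction problems (graph coloring,
    Sudoku, Ising spin systems) into noisy winner-take-all spiking neural
    networks, simulates them with a discrete-time leaky integrate-and-fire
    model with exponential post-synaptic currents and scheduled Poisson noise,
    and analyses the resulting spike trains (decoded network microstates,
    Shannon entropy, firing rate, visited-state counts, convergence-time
    statistics). Includes exact brute-force oracles for small instances and
    bundled benchmark fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
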