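# snncsp

Stochastic spiking neural network solvers for binary constraint
satisfaction problems (CSPs), in R.

Many hard combinatorial problems — map coloring, Sudoku, finding
low-energy states of Ising spin glasses — are binary CSPs ⟨X, D, C⟩:
variables X with value domains D, related by pairwise constraints C that
either forbid (negative) or demand (positive) equal values. `snncsp`
implements a neuromorphic-style solver for such problems: the CSP is
compiled into a network of leaky integrate-and-fire (LIF) neuron
populations in which

* each (variable, value) pair is a sub-population of `n` neurons,
* the sub-populations of one variable form a winner-take-all circuit
  through lateral inhibition,
* negative constraints become inhibitory (and positive constraints
  excitatory) projections between equal-value sub-populations, and
* Poisson noise populations drive a stochastic search over network states,
  with a scheduled dissipation phase acting as an annealing window.

The network is simulated in discrete 1 ms steps (exponential post-synaptic
currents, membrane equation τ_m du/dt = −u + R·I), spikes are binned into
200 ms windows, each variable is decoded as its most active value
(winner-take-all readout), and each decoded solution is independently
re-verified against the constraints. Satisfying configurations are
attractors of the dynamics: once found, they persist. The package is aimed
at people studying stochastic search in spiking networks — it solves CSPs
honestly, but a problem-specific backtracking solver will beat it by orders
of magnitude; that is not the point.

## Worked example

Three-color the adjacency graph of Canada's 13 provinces and territories
(bundled as a fixture), 20 independent runs:

```r
library(snncsp)

ps <- preset_params("coloring", current = 0.17)
exp <- run_experiment("canada", params = ps$params, lif = ps$lif,
                      duration = 30000, n_runs = 20, seed = 1,
                      mode = "first")
exp$stats
#> Runs: 20, successes: 20 (xi = 1.00)
#>   mu = 1.81, sigma = 0.5486, gamma1 = -1.996, t_min = 0.2
```

All 20 runs converge (success ratio ξ = 1.00) with a mean model time to
the first verified satisfying coloring of 1.81 s (best run 0.2 s) — the
solver finds and then *stays* in a proper coloring. A single run with full
diagnostics:

```r
sol <- solve_csp("canada", params = ps$params, lif = ps$lif,
                 duration = 10000, seed = 1)
sol$labels            # decoded color per region, e.g. "0" "1" "2" ...
plot(sol$trace)       # entropy / firing rate / visited-states panels
```

Other fixtures: `list_fixtures()` — Australia and a synthetic world-scale
map, easy/hard Sudoku and AI Escargot, antiferromagnetic rings,
ferromagnetic lattices and 2-D spin glasses. Sudoku clues are encoded by
exclusive stimulation and are preserved by construction:

```r
ps <- preset_params("sudoku")
exp <- run_experiment("sudoku-easy", params = ps$params, lif = ps$lif,
                      duration = 120000, n_runs = 10, seed = 1)
```

Spin systems come back as energies: a frustrated 10×10 spin glass
(`load_fixture("lattice-2d")`) quenches into a frozen configuration whose
Ising energy lies far below the mean over random configurations.

A thin command-line interface over the same functions ships in
`inst/cli/snncsp` (verbs: `fixtures`, `inspect`, `solve`, `experiment`,
`verify`).

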