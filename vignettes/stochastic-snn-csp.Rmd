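---
title: "Solving constraint satisfaction problems with stochastic spiking networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Solving constraint satisfaction problems with stochastic spiking networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snncsp)
```

## The model

A binary constraint satisfaction problem (CSP) is a tuple ⟨X, D, C⟩ of
variables, per-variable value domains, and signed pairwise constraints: a
*negative* constraint forbids two variables from taking equal values (map
coloring, Sudoku), a *positive* one requires equality (ferromagnetic spin
couplings). `snncsp` turns such a problem into a stochastic spiking neural
network whose dynamics perform the search, and reads the answer back out of
the spike trains.

The translation assigns every (variable, domain value) pair a
sub-population of `n_ensemble` leaky integrate-and-fire (LIF) neurons.
Three kinds of projections shape the energy landscape:

* **Winner-take-all (WTA) lateral inhibition** between all sub-populations
  of one variable, so that on average a single value stays active per
  variable;
* **constraint projections** between equal-value sub-populations of two
  constrained variables — inhibitory for negative constraints, excitatory
  for positive ones, instantiated in both directions;
* **noise projections** from Poisson generator populations, which inject
  the energy that drives the search.

Each neuron follows the normalized LIF equation
τ_m du/dt = −u + R·I(t), firing when u crosses the threshold u_th = 1 from
below and resetting to u_r = 0. Every presynaptic spike injects an
exponential post-synaptic current (q/τ)·e^(−t/τ)·Θ(t) scaled by the synapse
weight, arriving after a synaptic delay of 1–2 ms. Simulation proceeds in
fixed 1 ms steps with an exponential-Euler membrane update and the synaptic
current held piecewise-constant over each step; the update is therefore
exact for constant input, and the per-neuron synaptic state is a single
exponentially decaying accumulator (mathematically identical to summing the
PSC kernels, by linearity).

The network state is read out in 200 ms bins: in each bin, each variable is
decoded as the domain whose sub-population spiked strictly most, with ties
and silence decoded as *undecided* — satisfaction is never granted on
ambiguous activity, and every decoded solution is re-verified against the
CSP by an explicit constraint scan before it is reported.

## How the search works

With only constant background current the network would be silent: the
external current I (0–0.3 in the presets) is deliberately subthreshold.
Activity comes from the stimulation noise sources. The package's noise
design, chosen once and used by all presets, is:

* one **continuous stimulation population** per principal sub-population
  (40 Poisson generators at 100 Hz, connected with probability 0.5), whose
  mean drive pushes neurons over threshold so the WTA circuits can act;
* one **dissipation population** per sub-population, active only during an
  initial *annealing window* (2 s by default), which partially cancels the
  stimulation early on.

During the annealing window the effective drive is weak, fluctuations
dominate, and the network drifts through configurations; violated
constraints feed inhibition into exactly the sub-populations that cause
them, so consistent configurations are favored. When the window closes the
full drive locks the configuration in: in a satisfying state no constraint
projection is active between winners, so winners fire undisturbed and all
competitors stay suppressed — satisfied states are attractors and the
convergence is stable. A frustrated system (an unsatisfiable CSP) instead
quenches into a local minimum, exactly like a spin glass cooled past its
freezing point. The schedule is the discrete-noise-control strategy the
solver is built around: stimulation pulses inject energy and can restart
the search, dissipation drains it.

Because the initial ramp-up acts as the annealing phase, most solve times
for small problems land just after the window closes; the window length
(`anneal_ms`) is the main knob trading search time against solution
quality. For problems where a single quench often lands in a local minimum
(Sudoku at desk scale), the preset re-opens the dissipation window
periodically (`anneal_period_ms`, 15 s for the Sudoku preset): a frozen
run melts, wanders and re-quenches — a scheduled restart implemented
purely through discontinuous noise, and a run is a sequence of nearly
independent annealing cycles.

## Parameters and presets

`preset_params(family)` returns the compiler and neuron parameters used for
the three bundled benchmark families. The weight ranges follow the
published per-problem tables for the map-coloring benchmarks; ranges are
magnitude bounds [low, high] sampled uniformly per synapse, with the sign
applied by projection class.

| preset | n_ensemble | WTA weights | constraint weights | I | q_scale |
|---|---|---|---|---|---|
| `coloring` | 20 | 1.2–1.5 | 1.2–1.4 | 0.17 (0.2 for Australia) | 2 |
| `sudoku` | 10 | 1.2–1.5 | 1.2–1.4 | 0.3 | 2 |
| `spin` | 50 | 0.1–0.2 | 0.1–0.2 | 0 | 8 |

Notes on the genuinely open choices:

* **Connection probability** `p_conn = 0.5` per neuron pair for every
  projection class. Only "random connections between populations" is
  documented upstream; published synapse totals cannot be inverted to a
  unique rule, so structural totals are not reproduction targets.
* **Per-event charge** `q_scale` sets the strength of recurrent synapses
  relative to the noise drive (noise weights are scaled as 0.75/q and
  0.55/q so the noise statistics are identical across presets). Larger q
  deepens the attractors: q = 2 gives the coloring benchmarks stable
  convergence at ensemble size 20; the spin preset uses q = 8, which
  quenches ferromagnets essentially instantly (the "very low noise"
  regime).
* **Ensemble size.** Stability of the decoded state is governed by how
  well `n_ensemble` averages the noise: at n = 5–10 decoded states flicker,
  at n = 20+ satisfied states persist indefinitely. The sudoku preset uses
  n = 10 (7,290 principal neurons instead of the published-scale ≈36k) to
  keep desk runs in minutes; consequently it also uses the coloring-scale
  weight ranges — the published Sudoku row (magnitudes ≤ 0.08) is
  calibrated for 50-neuron ensembles and noise rates that were never
  published, and at n = 10 it produces no winner-take-all separation at
  all.
* **Spin weights.** The published spin rows print the range [−0.2, −0.0];
  draws near zero make a synapse ineffective, and at desk scales the full
  range quenches indecisively. The preset uses the upper half of the
  printed range, [0.1, 0.2].
* **Delays** are uniform on [1, 2] ms (no published values; the 1 ms floor
  is one time step). **Refractory period** defaults to 2 ms, standard LIF
  practice, configurable to 0. **Membrane constants** τ_m = 20 ms,
  τ_syn = 5 ms are conventional values on the normalized scale; none are
  published.
* **Clue encoding** (Sudoku givens) is by exclusive stimulation: a clued
  cell keeps noise drive only on its clued digit, plus a bias current
  (`clue_bias = 0.3`). No encoding is described upstream; this one makes
  clue preservation a structural property rather than a dynamical hope.

## Worked example

```{r canada, eval = FALSE}
ps <- preset_params("coloring", current = 0.17)
exp <- run_experiment("canada", params = ps$params, lif = ps$lif,
                      duration = 30000, n_runs = 20, seed = 1,
                      mode = "first")
exp$stats
#> Runs: 20, successes: 20 (xi = 1.00)
#>   mu = 1.81, sigma = 0.5486, gamma1 = -1.996, t_min = 0.2
```

Twenty independent runs of the 13-region Canada map three-coloring all
converge (ξ = 1), with a mean first-satisfaction time of 1.8 s of model
time — the same order as the published ≈0.9 s for this benchmark. A single
run can be inspected with `solve_csp()` and `plot()` on its trace, which
reproduces the standard three-panel entropy / firing-rate / states-count
view of the search.

## What the observables mean

* **Entropy S(t)**: Shannon entropy (bits) of the empirical distribution
  of decoded microstates over a trailing window (default: the full history
  up to t). It falls to 0 when the network settles into one state. The
  microstate here is the variable-level decoded assignment, not the
  per-neuron binary vector: the latter's distribution is not estimable
  from a single run (the support is astronomically large), while the
  decoded version shows the same qualitative convergence signature. A
  sliding window is selectable.
* **Activity ν(t)**: mean firing rate per principal neuron per bin.
* **Ω(t)**: cumulative count of distinct decoded states, with flags for
  new states, revisits and bin-to-bin changes.
* **Solve times**: `first` is the start of the earliest satisfying bin;
  `stable` the start of the earliest satisfying bin from which every later
  bin also satisfies (the network may hop between distinct solutions, but
  never back to violation). Multi-run summaries report the success ratio
  ξ over all runs and μ, σ, adjusted Fisher–Pearson skewness γ₁ and t_min
  over the successful ones.

## What the benchmarks do and do not show

The bundled fixtures reproduce the study's *conditions*, not its exact
instances where those were never published in machine-readable form: the
world-map border list and the easy/hard Sudoku grids are replaced by
synthetic stand-ins of the same shape (a seeded 193-vertex planar graph; generated puzzles with 36
and 26 clues and verified unique solutions), labelled synthetic in their
filenames. AI Escargot is the published puzzle. Published network-size
totals (Table-style neuron/synapse counts) are not reproducible because the
ensemble and connectivity conventions behind them are under-specified, and
are deliberately not targets; the structural counts that *are* exact —
populations, domain sizes, constraint counts, projection counts — are
tested exhaustively.

Problem sizes in the test suite are chosen to keep a full run on one CPU
in minutes: Canada at ensemble size 20 (780 principal neurons, the
published scale for this benchmark), Sudoku at ensemble size 10, lattices
at 15–25 neurons per spin state. The simulator itself handles the
published Sudoku scale (≈37k neurons, ≈86M synapses), but a hundred
repeated runs at that scale is a cluster-day, not a desk-minute; the
mean-solve-time claims at full Sudoku scale are therefore not checked,
only the scaled-down substitute behavior (solves with preserved clues in a
majority of runs).

## Numerical choices and degenerate inputs

* Time step fixed at 1 ms; bins are half-open [k·w, (k+1)·w) with w =
  200 ms by default.
* The firing condition is a strict crossing (u > u_th), so a neuron
  driven exactly to rheobase never fires, matching the continuous-time
  model.
* Poisson noise is one Bernoulli trial per generator per step
  (p = rate·dt, rejected if p > 1), from a counter-based RNG keyed by
  (seed, source, step): streams are independent per source, adding or
  removing sources never perturbs other streams, and chunked simulation
  reproduces monolithic runs exactly.
* Decode ties are undecided, never arbitrary winners. For final spin maps
  of frustrated systems, `final_assignment()` pools the trailing bins
  (1–2 s) before decoding, which resolves marginally driven "free" spins
  without ever inventing a winner within a bin.
* An all-`NA` (never-satisfied) run reports a not-converged marker; moment
  statistics over zero or one successes are reported as `NA`, never
  fabricated.
* Lattices are open-boundary (finite blocks); the antiferromagnetic ring
  fixture closes a 10-spin chain into a ring, whose alternating optimum
  satisfies all 10 bonds (energy −10·U by exhaustive enumeration).
* Ordering conventions: graph vertices by first appearance in the edge
  list, Sudoku cells row-major, lattice sites column-major linear index;
  brute-force enumeration is lexicographic with variable 1 most
  significant.

## Known limitations

* The solver is a stochastic search: completeness holds only in the limit
  of infinite time, and unsatisfiable instances are indistinguishable from
  hard ones except by timeout (the frustrated-quench diagnostics help for
  spin systems).
* Weight ranges and noise schedules interact; presets are calibrated per
  problem family, and new problem classes will generally need their own
  calibration (the annealing window and q_scale first).
* Only binary constraints are supported; k-ary constraints, soft/weighted
  semantics and inequality constraints are out of scope.
* The decoded-state entropy is a proxy for the network's true state-space
  entropy; it underestimates activity at the neuron level by construction.
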