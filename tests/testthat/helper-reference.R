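# Independent plain-R reference implementations used as oracles. These
# deliberately re-derive the dynamics by direct evaluation (explicit kernel
# sums, direct constraint scans) rather than reusing the package's internals.

# Reference LIF network simulator: exponential-Euler membrane update with the
# synaptic current obtained by explicitly summing the exponential PSC kernel
# over all past spike arrivals (no decaying accumulator).
ref_simulate <- function(n, synapses, I, lif, duration) {
  u <- rep(lif$u_r, n)
  refr <- rep(0L, n)
  alpha <- exp(-1 / lif$tau_m)
  arrivals <- list()  # per neuron: vector of (arrival time, weight)
  arr_t <- rep(list(numeric(0)), n)
  arr_w <- rep(list(numeric(0)), n)
  sp_t <- integer(0); sp_i <- integer(0)
  syn_by_pre <- split(seq_len(nrow(synapses)), synapses$pre)
  for (t in 0:(duration - 1)) {
    cur <- vapply(seq_len(n), function(i) {
      if (!length(arr_t[[i]])) return(0)
      dt <- t - arr_t[[i]]
      sum(ifelse(dt >= 0,
                 arr_w[[i]] * (lif$q_scale / lif$tau_syn) *
                   exp(-dt / lif$tau_syn), 0))
    }, numeric(1))
    fired <- integer(0)
    for (i in seq_len(n)) {
      if (refr[i] > 0) { refr[i] <- refr[i] - 1L; u[i] <- lif$u_r; next }
      u[i] <- u[i] * alpha + (1 - alpha) * lif$R * (I[i] + cur[i])
      if (u[i] > lif$u_th) {
        fired <- c(fired, i)
        u[i] <- lif$u_r
        refr[i] <- lif$t_ref
      }
    }
    for (i in fired) {
      sp_t <- c(sp_t, t); sp_i <- c(sp_i, i)
      rows <- syn_by_pre[[as.character(i - 1L)]]  # synapse pre ids 0-based
      for (r in rows) {
        post <- synapses$post[r] + 1L
        arr_t[[post]] <- c(arr_t[[post]], t + synapses$delay[r])
        arr_w[[post]] <- c(arr_w[[post]], synapses$weight[r])
      }
    }
  }
  data.frame(time_ms = sp_t, neuron = sp_i)
}

# Build a small hand-specified network_spec: `pops` sub-populations of one
# neuron each, an explicit synapse table, per-population currents, no noise.
toy_network <- function(n_pops, synapses, currents) {
  x <- csp(domains = rep(list("v"), n_pops))
  params <- compiler_params(n_ensemble = 1, current = 0, stim = NULL,
                            diss = NULL)
  net <- compile_network(x, params, seed = 1)
  net$synapses <- synapses
  net$currents <- currents
  net
}

# Independent Sudoku legality check used to validate check_assignment.
ref_sudoku_ok <- function(digits) {
  g <- matrix(digits, 9, 9, byrow = TRUE)
  ok <- TRUE
  for (i in 1:9) {
    ok <- ok && !anyDuplicated(g[i, ]) && !anyDuplicated(g[, i])
  }
  for (br in 0:2) for (bc in 0:2) {
    ok <- ok && !anyDuplicated(as.vector(g[br * 3 + 1:3, bc * 3 + 1:3]))
  }
  ok
}

# Count frustrated bonds of a spin configuration directly.
ref_frustrated <- function(system, spins) {
  b <- system$bonds
  sum(b$J * spins[b$i] * spins[b$j] < 0)
}

# Random small CSP generator for property tests.
random_csp <- function(seed) {
  set.seed(seed)
  n <- sample(2:5, 1)
  dsz <- sample(2:4, 1)  # equal domain sizes so the compiler accepts it
  pairs <- t(combn(n, 2))
  keep <- sample(nrow(pairs), sample(seq_len(nrow(pairs)), 1))
  csp(domains = rep(list(as.character(seq_len(dsz))), n),
      constraints = data.frame(i = pairs[keep, 1], j = pairs[keep, 2],
                               sign = sample(c(-1, 1), length(keep),
                                             replace = TRUE)))
}
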