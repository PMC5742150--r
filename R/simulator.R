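#' Leaky integrate-and-fire neuron parameters
#'
#' The membrane potential follows
#' \eqn{\tau_m \, du/dt = -u(t) + R I(t)}, on a normalized scale: reset at
#' \code{u_r = 0}, threshold at \code{u_th = 1}. Each presynaptic spike
#' injects an exponential post-synaptic current
#' \eqn{j(t) = (q/\tau) e^{-t/\tau}\Theta(t)} carrying total charge \code{q},
#' scaled by the synapse weight. The simulation time step is fixed at 1 ms.
#'
#' @param tau_m membrane time constant, ms.
#' @param R membrane resistance (normalized units).
#' @param u_th spike threshold.
#' @param u_r reset potential.
#' @param tau_syn PSC decay time constant \eqn{\tau}, ms.
#' @param q_scale total PSC charge \code{q} per unit synaptic weight.
#' @param t_ref absolute refractory period, ms (0 disables it).
#' @param dt integration step; fixed at 1 ms.
#' @return list of class \code{"lif_params"}.
#' @export
lif_params <- function(tau_m = 20, R = 1, u_th = 1, u_r = 0, tau_syn = 5,
                       q_scale = 1, t_ref = 2, dt = 1) {
  if (dt != 1) stop("the simulator runs at a fixed 1 ms time step")
  if (tau_m <= 0 || tau_syn <= 0) stop("time constants must be positive")
  if (u_th <= u_r) stop("threshold must exceed the reset potential")
  if (t_ref < 0) stop("refractory period must be >= 0")
  structure(list(tau_m = tau_m, R = R, u_th = u_th, u_r = u_r,
                 tau_syn = tau_syn, q_scale = q_scale,
                 t_ref = as.integer(t_ref), dt = 1),
            class = "lif_params")
}

#' Simulation configuration
#'
#' @param duration total simulated model time, ms (positive multiple of the
#'   1 ms step).
#' @param seed integer master seed for all noise sources.
#' @param record_v optional integer vector of principal neuron ids (1-based)
#'   whose membrane traces are recorded.
#' @return list of class \code{"sim_config"}.
#' @export
sim_config <- function(duration = 1000, seed = 1L, record_v = integer(0)) {
  if (duration <= 0 || duration != round(duration))
    stop("'duration' must be a positive whole number of ms")
  structure(list(duration = as.integer(duration), seed = as.integer(seed),
                 record_v = as.integer(record_v)),
            class = "sim_config")
}

#' Exponential post-synaptic current kernel
#'
#' \eqn{j(t) = (q/\tau) e^{-t/\tau} \Theta(t)}: zero before the spike
#' arrives, peak \code{q/tau_syn} at arrival, exponential decay after. The
#' integral over all time is the total transferred charge \code{q}.
#'
#' @param t time since spike arrival, ms (vectorized).
#' @param lif [lif_params()].
#' @return current at time \code{t}.
#' @export
psc_kernel <- function(t, lif = lif_params()) {
  ifelse(t >= 0, (lif$q_scale / lif$tau_syn) * exp(-t / lif$tau_syn), 0)
}

#' Seeded Poisson event times
#'
#' Discrete-time Poisson process at the simulator's 1 ms resolution: one
#' Bernoulli trial per step with success probability \code{rate_hz * dt},
#' restricted to the given window. Identical \code{(rate, window, seed)}
#' give identical events.
#'
#' @param rate_hz event rate in Hz; \code{rate_hz/1000} must not exceed 1.
#' @param window \code{c(start_ms, duration_ms)}.
#' @param seed integer seed.
#' @return numeric vector of event times, ms.
#' @export
poisson_events <- function(rate_hz, window, seed = 1L) {
  if (rate_hz < 0) stop("'rate_hz' must be >= 0")
  p <- rate_hz * 1e-3
  if (p > 1)
    stop("rate * dt exceeds 1; a Bernoulli step process cannot represent it")
  start <- window[1]; dur <- window[2]
  if (dur <= 0 || p == 0) return(numeric(0))
  steps <- as.integer(dur)
  hit <- local_seed(seed, stats::runif(steps) < p)
  start + (which(hit) - 1)
}

# Internal: precompute the CSR synapse layout and LIF constants once so
# repeated (chunked) simulation of one network avoids re-sorting synapses.
sim_prepare <- function(network, lif) {
  stopifnot(inherits(network, "network_spec"), inherits(lif, "lif_params"))
  syn <- network$synapses
  np <- network$n_principal
  ns <- network$noise_sources
  ntot <- np
  if (nrow(ns) > 0L) ntot <- max(ntot, max(ns$offset + ns$size))
  ord <- order(syn$pre)
  pre <- syn$pre[ord]; post <- syn$post[ord]
  if (length(post) && (min(post) < 0 || max(post) >= np))
    stop("synapse targets must be principal neurons")
  counts <- tabulate(pre + 1L, nbins = ntot)
  row_ptr <- c(0L, cumsum(counts))
  if (nrow(ns) > 0L) {
    # gid = the generator's global neuron id as assigned at compile time;
    # sources removed later (e.g. clue encoding) leave gaps, so gids are
    # carried explicitly rather than re-enumerated
    nz <- data.frame(
      gid = rep(ns$offset, ns$size) + unlist(lapply(ns$size, seq_len)) - 1L,
      stream = rep(ns$source, ns$size) * 100000L +
        unlist(lapply(ns$size, seq_len)),
      p = rep(ns$rate_hz, ns$size) * 1e-3,
      start = rep(ns$start_ms, ns$size),
      end = rep(ns$start_ms + ns$duration_ms, ns$size))
    if (any(nz$p > 1))
      stop("noise rate * dt exceeds 1")
  } else {
    nz <- data.frame(gid = integer(), stream = integer(), p = numeric(),
                     start = numeric(), end = numeric())
  }
  max_delay <- max(2L, if (length(ord)) max(syn$delay) else 2L)
  pop_of_neuron <- rep(network$populations$pop,
                       each = network$params$n_ensemble)
  list(np = np, post = as.integer(post), w = as.numeric(syn$weight[ord]),
       delay = as.integer(syn$delay[ord]), row_ptr = as.integer(row_ptr),
       I = rep(network$currents, each = network$params$n_ensemble),
       nz = nz, max_delay = max_delay,
       alpha = exp(-lif$dt / lif$tau_m), beta = exp(-lif$dt / lif$tau_syn),
       lif = lif, pop_of_neuron = pop_of_neuron)
}

sim_init_state <- function(prep) {
  list(u = rep(prep$lif$u_r, prep$np), c = rep(0, prep$np),
       ref = rep(0L, prep$np),
       buf = matrix(0, prep$max_delay + 1L, prep$np),
       step = 0L)
}

# Internal: advance a prepared simulation by n_steps, returning raw spikes
# and the carried-over state.
sim_run_chunk <- function(prep, state, n_steps, seed, record_v = integer(0)) {
  nz <- prep$nz
  end <- pmin(nz$end, Inf)
  res <- .sim_core(prep$np, prep$post, prep$w, prep$delay, prep$row_ptr,
                   prep$I,
                   as.integer(nz$gid), as.integer(nz$stream), nz$p,
                   as.integer(pmax(nz$start, 0)),
                   as.integer(pmin(end, 2147483000)),
                   prep$alpha, prep$beta, prep$lif$R, prep$lif$u_th,
                   prep$lif$u_r,
                   prep$lif$q_scale / prep$lif$tau_syn, prep$lif$t_ref,
                   state$step, as.integer(n_steps), prep$max_delay,
                   as.numeric(seed) %% 2^53,
                   state$u, state$c, state$ref, state$buf,
                   as.integer(record_v) - 1L)
  list(spike_step = res$spike_step, spike_neuron = res$spike_neuron + 1L,
       vm = res$vm,
       state = list(u = res$u, c = res$c, ref = res$ref, buf = res$buf,
                    step = state$step + as.integer(n_steps)))
}

#' Simulate a compiled spiking network
#'
#' Runs the discrete-time (1 ms) LIF simulation of a compiled network:
#' at every step each principal neuron integrates its leak, constant drive,
#' the exponentially decaying synaptic current fed by delayed spikes from
#' other principal neurons, and scheduled Poisson noise events; threshold
#' crossings emit spikes, reset the membrane and start the refractory period.
#' The run is fully deterministic given \code{(network, lif, config)}.
#'
#' @param network a \code{"network_spec"} from [compile_network()].
#' @param lif [lif_params()].
#' @param config [sim_config()].
#' @return object of class \code{"spike_record"}: principal-neuron spike
#'   events (time ms, neuron id, population id), sorted by time, plus the
#'   population table and optional membrane traces (\code{$vm}).
#' @export
simulate_network <- function(network, lif = lif_params(),
                             config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  prep <- sim_prepare(network, lif)
  state <- sim_init_state(prep)
  out <- sim_run_chunk(prep, state, config$duration, config$seed,
                       config$record_v)
  spike_record(time_ms = as.numeric(out$spike_step),
               neuron = out$spike_neuron,
               pop = prep$pop_of_neuron[out$spike_neuron],
               duration = config$duration, n_principal = prep$np,
               populations = network$populations,
               vm = if (length(config$record_v)) out$vm else NULL)
}

spike_record <- function(time_ms, neuron, pop, duration, n_principal,
                         populations, vm = NULL) {
  structure(list(time_ms = time_ms, neuron = neuron, pop = pop,
                 duration = duration, n_principal = n_principal,
                 populations = populations, vm = vm, dt = 1),
            class = "spike_record")
}

#' @export
print.spike_record <- function(x, ...) {
  cat(sprintf("Spike record: %d events from %d principal neurons over %d ms (%.2f Hz mean rate)\n",
              length(x$time_ms), x$n_principal, x$duration,
              length(x$time_ms) / x$n_principal / (x$duration / 1000)))
  invisible(x)
}

#' @export
as.data.frame.spike_record <- function(x, ...) {
  data.frame(time_ms = x$time_ms, neuron = x$neuron, pop = x$pop)
}

#' Write spike events as a tab-separated table
#'
#' Columns: \code{time_ms}, \code{neuron}, \code{population}.
#'
#' @param x a \code{"spike_record"}.
#' @param path output file.
#' @export
write_spikes <- function(x, path) {
  stopifnot(inherits(x, "spike_record"))
  utils::write.table(as.data.frame(x), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
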