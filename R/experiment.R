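# Coerce a problem argument (csp, spin system or fixture name) to a csp.
as_csp <- function(problem) {
  if (inherits(problem, "csp")) return(problem)
  if (inherits(problem, "spin_system")) return(csp_from_spin_system(problem))
  if (is.character(problem) && length(problem) == 1L)
    return(as_csp(load_fixture(problem)))
  stop("'problem' must be a csp, a spin_system or a fixture name")
}

#' Run a repeated-run solver experiment
#'
#' Compiles the problem once, then performs \code{n_runs} independent
#' simulations (noise seed = \code{seed + run index}), decodes each run into
#' a per-bin state trace, extracts its convergence time and aggregates the
#' [experiment_stats()] over all runs. Every run that reports satisfaction is
#' re-verified against the CSP with [check_assignment()]; a decoded
#' "solution" failing re-verification is an internal inconsistency and
#' raises an error.
#'
#' With \code{early_stop = TRUE} (the default for \code{mode = "first"}),
#' each run is simulated in chunks and stops at the first satisfying bin,
#' which leaves later bins unobserved; use \code{mode = "stable"} (full
#' duration) when stability of the convergence matters.
#'
#' @param problem a \code{"csp"}, a \code{"spin_system"} or a fixture name.
#' @param params [compiler_params()].
#' @param lif [lif_params()].
#' @param duration maximum model time per run, ms.
#' @param n_runs number of runs.
#' @param seed master seed; run r uses noise seed \code{seed + r}.
#' @param mode convergence definition passed to [solve_time()].
#' @param early_stop stop a run at its first satisfying bin (only for
#'   \code{mode = "first"}).
#' @param bin_width analysis bin width, ms.
#' @param chunk_ms simulation chunk length for early stopping (multiple of
#'   \code{bin_width}).
#' @param use_clues encode the CSP's clues via [encode_clues()].
#' @param keep_traces keep each run's \code{"state_trace"} in the result.
#' @param out_dir if given, write per-run trace tables, solutions and the
#'   aggregate statistics there.
#' @return object of class \code{"csp_experiment"}: \code{$stats} (a
#'   \code{"run_stats"} over solve times in seconds of model time),
#'   \code{$runs} (per-run records) and the resolved configuration.
#' @export
run_experiment <- function(problem, params = compiler_params(),
                           lif = lif_params(), duration = 10000,
                           n_runs = 20, seed = 1L,
                           mode = c("first", "stable"),
                           early_stop = NULL, bin_width = 200,
                           chunk_ms = 1000, use_clues = TRUE,
                           keep_traces = FALSE, out_dir = NULL) {
  mode <- match.arg(mode)
  if (is.null(early_stop)) early_stop <- mode == "first"
  if (early_stop && mode == "stable")
    stop("stable convergence needs the full duration; set early_stop = FALSE")
  if (n_runs < 1) stop("'n_runs' must be >= 1")
  if (chunk_ms %% bin_width != 0)
    stop("'chunk_ms' must be a multiple of 'bin_width'")
  x <- as_csp(problem)
  network <- compile_network(x, params, seed = seed)
  if (use_clues && !is.null(x$clues)) network <- encode_clues(network)
  prep <- sim_prepare(network, lif)

  runs <- vector("list", n_runs)
  times_ms <- rep(NA_real_, n_runs)
  for (r in seq_len(n_runs)) {
    run_seed <- seed + r
    if (early_stop) {
      sim <- sim_until_satisfied(prep, network, x, duration, run_seed,
                                 bin_width, chunk_ms)
    } else {
      rec <- simulate_network(network, lif,
                              sim_config(duration = duration,
                                         seed = run_seed))
      sim <- list(trace = state_trace(rec, x, bin_width = bin_width),
                  duration = duration)
    }
    tr <- sim$trace
    t_ms <- solve_time(tr, mode)
    sol <- NULL
    if (!is.na(t_ms)) {
      sat_bins <- which(tr$table$satisfied)
      sol <- tr$states[, sat_bins[length(sat_bins)]]
      chk <- check_assignment(x, sol)
      if (!chk$satisfied)
        stop("internal inconsistency: run ", r, " reported satisfaction ",
             "but its decoded solution fails re-verification")
    }
    times_ms[r] <- t_ms
    runs[[r]] <- list(run = r, seed = run_seed, solve_time_ms = t_ms,
                      satisfied = !is.na(t_ms), solution = sol,
                      simulated_ms = sim$duration,
                      trace = if (keep_traces) tr else NULL)
  }
  stats <- experiment_stats(times_ms / 1000)
  out <- structure(list(stats = stats, runs = runs, csp = x,
                        network_summary = network_summary(network),
                        config = list(params = params, lif = lif,
                                      duration = duration, n_runs = n_runs,
                                      seed = seed, mode = mode,
                                      early_stop = early_stop,
                                      bin_width = bin_width)),
                   class = "csp_experiment")
  if (!is.null(out_dir)) write_experiment(out, out_dir, runs_full = runs)
  out
}

# Chunked simulation that stops at the first satisfying bin.
sim_until_satisfied <- function(prep, network, x, duration, seed, bin_width,
                                chunk_ms) {
  state <- sim_init_state(prep)
  times <- numeric(0); neurons <- integer(0)
  done_ms <- 0
  trace <- NULL
  while (done_ms < duration) {
    step_ms <- min(chunk_ms, duration - done_ms)
    out <- sim_run_chunk(prep, state, step_ms, seed)
    state <- out$state
    times <- c(times, as.numeric(out$spike_step))
    neurons <- c(neurons, out$spike_neuron)
    done_ms <- done_ms + step_ms
    rec <- spike_record(times, neurons, prep$pop_of_neuron[neurons],
                        duration = done_ms, n_principal = prep$np,
                        populations = network$populations)
    trace <- state_trace(rec, x, bin_width = bin_width)
    if (any(trace$table$satisfied)) break
  }
  list(trace = trace, duration = done_ms)
}

#' @export
print.csp_experiment <- function(x, ...) {
  cat(sprintf("CSP experiment: %d runs of up to %.1f s model time (%s convergence)\n",
              x$config$n_runs, x$config$duration / 1000, x$config$mode))
  print(x$stats)
  invisible(x)
}

write_experiment <- function(exp, out_dir, runs_full) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_run_stats(exp$stats, file.path(out_dir, "run_stats.txt"))
  cfgpath <- file.path(out_dir, "config.txt")
  cfg <- exp$config
  writeLines(c("format snncsp-config 1",
               paste("n_runs", cfg$n_runs), paste("seed", cfg$seed),
               paste("duration_ms", cfg$duration),
               paste("mode", cfg$mode), paste("bin_width", cfg$bin_width),
               paste("early_stop", cfg$early_stop),
               paste("n_ensemble", cfg$params$n_ensemble),
               paste("p_conn", cfg$params$p_conn),
               paste("current", cfg$params$current),
               paste("wta_weight", paste(cfg$params$wta_weight, collapse = " ")),
               paste("constraint_weight",
                     paste(cfg$params$constraint_weight, collapse = " ")),
               paste("tau_m", cfg$lif$tau_m), paste("tau_syn", cfg$lif$tau_syn),
               paste("t_ref", cfg$lif$t_ref)), cfgpath)
  for (run in runs_full) {
    if (!is.null(run$trace))
      write_state_trace(run$trace,
                        file.path(out_dir, sprintf("run%03d_trace.tsv", run$run)))
    if (!is.null(run$solution))
      writeLines(paste(run$solution, collapse = " "),
                 file.path(out_dir, sprintf("run%03d_solution.txt", run$run)))
  }
  invisible(out_dir)
}

#' Solve a CSP with a single stochastic run
#'
#' Convenience wrapper: compile, simulate once, decode, verify. See
#' [run_experiment()] for repeated runs and statistics.
#'
#' @inheritParams run_experiment
#' @param trace_record keep the spike record in the result.
#' @return object of class \code{"csp_solution"}: \code{$satisfied},
#'   \code{$assignment} (domain indices), \code{$labels} (decoded value
#'   labels), \code{$solve_time_ms}, \code{$trace}.
#' @export
solve_csp <- function(problem, params = compiler_params(),
                      lif = lif_params(), duration = 10000, seed = 1L,
                      bin_width = 200, use_clues = TRUE,
                      trace_record = FALSE) {
  x <- as_csp(problem)
  network <- compile_network(x, params, seed = seed)
  if (use_clues && !is.null(x$clues)) network <- encode_clues(network)
  rec <- simulate_network(network, lif, sim_config(duration = duration,
                                                   seed = seed + 1L))
  tr <- state_trace(rec, x, bin_width = bin_width)
  t_ms <- solve_time(tr, "first")
  sol <- rep(NA_integer_, x$n_variables)
  if (!is.na(t_ms)) {
    sat_bins <- which(tr$table$satisfied)
    sol <- tr$states[, sat_bins[length(sat_bins)]]
    if (!check_assignment(x, sol)$satisfied)
      stop("internal inconsistency: satisfying bin fails re-verification")
  }
  structure(list(satisfied = !is.na(t_ms), assignment = sol,
                 labels = assignment_labels(x, sol),
                 solve_time_ms = t_ms, stable_time_ms = solve_time(tr, "stable"),
                 trace = tr, csp = x,
                 spikes = if (trace_record) rec else NULL),
            class = "csp_solution")
}

#' @export
print.csp_solution <- function(x, ...) {
  if (x$satisfied) {
    cat(sprintf("Satisfying assignment found at %.2f s (stable from %s s):\n",
                x$solve_time_ms / 1000,
                ifelse(is.na(x$stable_time_ms), "never",
                       format(x$stable_time_ms / 1000))))
    lab <- x$labels
    show <- min(length(lab), 20L)
    cat("  ", paste(x$csp$labels[seq_len(show)], "=", lab[seq_len(show)],
                    collapse = ", "), if (length(lab) > show) "..." else "",
        "\n")
  } else {
    cat("No satisfying assignment found within the simulated time.\n")
  }
  invisible(x)
}
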