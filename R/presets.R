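#' Benchmark parameter presets
#'
#' Ready-made compiler and neuron parameters for the three bundled problem
#' families, mirroring the per-problem weight ranges and external currents of
#' the reference benchmarks (map coloring, Sudoku, Ising spin systems). The
#' noise design is the same in all presets: one continuous stimulation
#' population per principal sub-population keeps the network active, and one
#' dissipation population, active only during an initial annealing window,
#' weakens the early drive so the winner-take-all circuits settle gradually
#' instead of locking into the first random configuration. After the window
#' closes the full drive locks the reached configuration in — satisfied
#' networks stay satisfied, frustrated ones quench.
#'
#' The per-event charge \code{q_scale} sets how strong the recurrent synapses
#' are relative to the noise drive (noise weights are chosen so the product
#' weight x charge, and hence the noise statistics, is the same in every
#' preset). Sudoku uses a larger charge because its printed weight ranges are
#' an order of magnitude smaller than the coloring ones and its ensembles are
#' scaled down to desk size.
#'
#' Sudoku uses \emph{cyclic} annealing: the dissipation window re-opens
#' every \code{anneal_period_ms}, so a run frozen in a local minimum melts
#' and re-quenches — a scheduled restart in the sense of discontinuous noise
#' control. The single-window presets simply use one cycle.
#'
#' @param family \code{"coloring"}, \code{"sudoku"} or \code{"spin"}.
#' @param n_ensemble override the preset ensemble size.
#' @param current override the external current (e.g. 0.2 for the Australia
#'   benchmark vs 0.17 for Canada).
#' @param anneal_ms length of each dissipation (annealing) window.
#' @param anneal_period_ms interval between window onsets (\code{NULL} = a
#'   single window at time 0); windows repeat up to \code{horizon_ms}.
#' @param horizon_ms latest window onset when annealing is cyclic.
#' @return list with elements \code{params} ([compiler_params()]) and
#'   \code{lif} ([lif_params()]).
#' @examples
#' ps <- preset_params("coloring")
#' \dontrun{
#' net <- compile_network(load_fixture("canada"), ps$params, seed = 1)
#' rec <- simulate_network(net, ps$lif, sim_config(10000, seed = 2))
#' }
#' @export
preset_params <- function(family = c("coloring", "sudoku", "spin"),
                          n_ensemble = NULL, current = NULL,
                          anneal_ms = 2000, anneal_period_ms = NULL,
                          horizon_ms = 120000) {
  family <- match.arg(family)
  base <- switch(family,
    coloring = list(n = 20, q = 2, wta = c(1.2, 1.5), con = c(1.2, 1.4),
                    I = 0.17),
    sudoku   = list(n = 10, q = 2, wta = c(1.2, 1.5), con = c(1.2, 1.4),
                    I = 0.3, period = 15000),
    spin     = list(n = 50, q = 8, wta = c(0.1, 0.2), con = c(0.1, 0.2),
                    I = 0))
  if (!is.null(n_ensemble)) base$n <- n_ensemble
  if (!is.null(current)) base$I <- current
  if (is.null(anneal_period_ms)) anneal_period_ms <- base$period  # or NULL
  starts <- if (is.null(anneal_period_ms)) 0
            else seq(0, horizon_ms, by = anneal_period_ms)
  # noise event charge held at weight*q = 0.75 (stim) / 0.55 (dissipation)
  stim_w <- 0.75 / base$q
  diss_w <- 0.55 / base$q
  params <- compiler_params(
    n_ensemble = base$n, p_conn = 0.5,
    wta_weight = base$wta, constraint_weight = base$con,
    current = base$I,
    stim = noise_params(size = 40, rate_hz = 100, weight = stim_w),
    diss = noise_params(size = 40, rate_hz = 100, weight = diss_w,
                        pulses = cbind(starts, anneal_ms)))
  list(params = params, lif = lif_params(q_scale = base$q))
}
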