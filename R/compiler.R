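#' Noise-source configuration
#'
#' Describes the stochastic Poisson populations attached to each principal
#' sub-population: either \emph{stimulation} (excitatory, injects energy so
#' the network explores its state space) or \emph{dissipation} (inhibitory,
#' drains activity to balance the energy budget). One source is instantiated
#' per (target sub-population, pulse).
#'
#' @param size number of independent Poisson generators per source.
#' @param rate_hz firing rate of each generator while its pulse is active.
#' @param weight synaptic strength magnitude of each noise event; applied
#'   positive for stimulation, negative for dissipation.
#' @param pulses two-column matrix of activation windows
#'   \code{(start_ms, duration_ms)}, non-overlapping and sorted;
#'   \code{Inf} duration means "until the end of the run".
#' @return list of class \code{"noise_params"}.
#' @export
noise_params <- function(size = 10, rate_hz = 100, weight = 1,
                         pulses = matrix(c(0, Inf), ncol = 2)) {
  pulses <- matrix(as.numeric(pulses), ncol = 2)
  if (nrow(pulses) > 0) {
    if (any(pulses[, 2] < 0)) stop("pulse durations must be >= 0")
    o <- order(pulses[, 1])
    pulses <- pulses[o, , drop = FALSE]
    if (nrow(pulses) > 1) {
      ends <- pulses[-nrow(pulses), 1] + pulses[-nrow(pulses), 2]
      if (any(ends > pulses[-1, 1]))
        stop("noise pulses must not overlap")
    }
  }
  if (size < 1) stop("noise source size must be >= 1")
  if (rate_hz < 0) stop("noise rate must be >= 0")
  structure(list(size = as.integer(size), rate_hz = rate_hz,
                 weight = abs(weight), pulses = pulses),
            class = "noise_params")
}

#' Compiler parameters
#'
#' Tunables of the CSP-to-network translation. Weight ranges are read as
#' magnitude bounds \code{[low, high]}; the compiler applies the sign that
#' the projection class dictates (winner-take-all and negative-constraint
#' projections are inhibitory, positive-constraint projections excitatory).
#' Per-synapse weights are drawn uniformly from the range and delays
#' uniformly from \code{delay_range} (floor 1 ms, one time step).
#'
#' @param n_ensemble neurons per (variable, domain) sub-population. Large
#'   ensembles average out spike noise and stabilize the winner-take-all
#'   readout.
#' @param p_conn connection probability per neuron pair within every
#'   projection.
#' @param wta_weight magnitude range for the lateral-inhibition synapses
#'   between a variable's domain sub-populations.
#' @param constraint_weight magnitude range for inter-variable constraint
#'   synapses.
#' @param delay_range synaptic delay range in ms.
#' @param current constant external drive per principal neuron (normalized
#'   membrane units; threshold is at 1).
#' @param stim stimulation [noise_params()], a list of them (e.g. a strong
#'   exploration pulse followed by a weak sustained source), or NULL for
#'   none.
#' @param diss dissipation [noise_params()], a list, or NULL for none.
#' @param clue_bias extra constant current given to the sub-population of a
#'   clued value by [encode_clues()].
#' @return list of class \code{"compiler_params"}.
#' @export
compiler_params <- function(n_ensemble = 20, p_conn = 0.5,
                            wta_weight = c(1.2, 1.5),
                            constraint_weight = c(1.2, 1.4),
                            delay_range = c(1, 2), current = 0.17,
                            stim = noise_params(),
                            diss = NULL, clue_bias = 0.3) {
  if (n_ensemble < 1) stop("'n_ensemble' must be >= 1")
  if (p_conn <= 0 || p_conn > 1) stop("'p_conn' must be in (0, 1]")
  if (delay_range[1] < 1) stop("delays must be >= 1 ms (one time step)")
  if (diff(delay_range) < 0 || diff(range(abs(wta_weight))) < 0)
    stop("ranges must be ordered")
  norm <- function(r) sort(abs(as.numeric(r)))
  as_noise_list <- function(x, what) {
    if (is.null(x)) return(NULL)
    if (inherits(x, "noise_params")) x <- list(x)
    if (!is.list(x) || !all(vapply(x, inherits, TRUE, "noise_params")))
      stop("'", what, "' must be a noise_params object or a list of them")
    x
  }
  stim <- as_noise_list(stim, "stim")
  diss <- as_noise_list(diss, "diss")
  structure(list(n_ensemble = as.integer(n_ensemble), p_conn = p_conn,
                 wta_weight = norm(wta_weight),
                 constraint_weight = norm(constraint_weight),
                 delay_range = as.numeric(delay_range),
                 current = current, stim = stim, diss = diss,
                 clue_bias = clue_bias),
            class = "compiler_params")
}

#' Compile a CSP into a stochastic spiking network description
#'
#' Translates a binary CSP into a network of leaky integrate-and-fire
#' populations: (a) one principal sub-population per (variable, domain
#' value), each with its scheduled Poisson stimulation (and, when configured,
#' dissipation) sources; (b) winner-take-all lateral inhibition between all
#' ordered pairs of a variable's sub-populations; (c) for every constraint,
#' projections between equal-domain sub-populations of its two variables in
#' both directions — inhibitory for negative constraints, excitatory for
#' positive ones. All synapse draws (connectivity, weights, delays) are a
#' pure function of \code{(csp, params, seed)}.
#'
#' @param x a \code{"csp"}.
#' @param params [compiler_params()].
#' @param seed integer seed for the connectivity/weight/delay draws.
#' @return object of class \code{"network_spec"}: populations, noise sources,
#'   projections, a synapse table (global neuron ids; principal neurons
#'   first), per-population currents, and the source CSP.
#' @export
compile_network <- function(x, params = compiler_params(), seed = 1L) {
  stopifnot(inherits(x, "csp"), inherits(params, "compiler_params"))
  n <- params$n_ensemble
  dsz <- vapply(x$domains, length, 1L)

  cons <- x$constraints
  if (nrow(cons) > 0L && any(dsz[cons$i] != dsz[cons$j]))
    stop("variables joined by a constraint must have equal domain sizes ",
         "(equal-domain pairing is undefined otherwise)")

  pops <- data.frame(pop = seq_len(sum(dsz)),
                     variable = rep(seq_along(dsz), dsz),
                     domain = unlist(lapply(dsz, seq_len)),
                     size = n)
  pops$offset <- (pops$pop - 1L) * n  # 0-based first-neuron id
  np <- nrow(pops)
  pop_of <- function(v, d) {
    # pops are laid out variable-major, domain-minor
    c(0L, cumsum(dsz))[v] + d
  }

  # projection table: winner-take-all then constraints, in CSP order
  src <- tgt <- integer(); cls <- character(); sgn <- numeric()
  for (v in seq_along(dsz)) {
    if (dsz[v] < 2L) next
    pr <- expand.grid(d1 = seq_len(dsz[v]), d2 = seq_len(dsz[v]))
    pr <- pr[pr$d1 != pr$d2, ]
    src <- c(src, pop_of(v, pr$d1)); tgt <- c(tgt, pop_of(v, pr$d2))
    cls <- c(cls, rep("wta", nrow(pr))); sgn <- c(sgn, rep(-1, nrow(pr)))
  }
  if (nrow(cons) > 0L) {
    for (r in seq_len(nrow(cons))) {
      d <- seq_len(dsz[cons$i[r]])
      pi <- pop_of(cons$i[r], d); pj <- pop_of(cons$j[r], d)
      src <- c(src, pi, pj); tgt <- c(tgt, pj, pi)
      cls <- c(cls, rep("constraint", 2L * length(d)))
      sgn <- c(sgn, rep(cons$sign[r], 2L * length(d)))
    }
  }
  proj <- data.frame(src = src, tgt = tgt, class = cls, sign = sgn)

  # noise sources: one per (target sub-population, config, pulse)
  mk_noise <- function(np_cfg, kind, sgn) {
    if (is.null(np_cfg) || nrow(np_cfg$pulses) == 0L) return(NULL)
    npul <- nrow(np_cfg$pulses)
    data.frame(target_pop = rep(pops$pop, each = npul),
               kind = kind, size = np_cfg$size, rate_hz = np_cfg$rate_hz,
               weight = sgn * np_cfg$weight,
               start_ms = rep(np_cfg$pulses[, 1], np),
               duration_ms = rep(np_cfg$pulses[, 2], np))
  }
  noise <- do.call(rbind, c(
    lapply(params$stim, mk_noise, kind = "stimulation", sgn = +1),
    lapply(params$diss, mk_noise, kind = "dissipation", sgn = -1)))
  if (is.null(noise))
    noise <- data.frame(target_pop = integer(), kind = character(),
                        size = integer(), rate_hz = numeric(),
                        weight = numeric(), start_ms = numeric(),
                        duration_ms = numeric())
  n_principal <- np * n
  if (nrow(noise) > 0L) {
    noise$source <- seq_len(nrow(noise))
    noise$offset <- n_principal + (noise$source - 1L) * noise$size
  }

  net <- local_seed(seed, {
    syn <- draw_projection_synapses(proj, pops, params)
    nsyn <- draw_noise_synapses(noise, pops, params)
    list(synapses = rbind(syn, nsyn))
  })

  structure(list(populations = pops, projections = proj,
                 noise_sources = noise, synapses = net$synapses,
                 currents = rep(params$current, np),
                 n_principal = n_principal,
                 n_noise = if (nrow(noise)) sum(noise$size) else 0L,
                 params = params, csp = x, seed = as.integer(seed)),
            class = "network_spec")
}

# Bernoulli connectivity with per-synapse uniform weights and delays for the
# principal projections. Returns 0-based pre/post global neuron ids.
draw_projection_synapses <- function(proj, pops, params) {
  n <- params$n_ensemble
  P <- nrow(proj)
  if (P == 0L)
    return(data.frame(pre = integer(), post = integer(), weight = numeric(),
                      delay = integer(), projection = integer()))
  per <- n * n
  keep <- stats::runif(P * per) <= params$p_conn
  kidx <- which(keep)
  p_id <- (kidx - 1L) %/% per + 1L          # projection of each kept pair
  within <- (kidx - 1L) %% per              # 0..n^2-1
  pre_l <- within %/% n                     # 0-based local pre index
  post_l <- within %% n
  lo <- ifelse(proj$class[p_id] == "wta", params$wta_weight[1],
               params$constraint_weight[1])
  hi <- ifelse(proj$class[p_id] == "wta", params$wta_weight[2],
               params$constraint_weight[2])
  w <- proj$sign[p_id] * stats::runif(length(kidx), lo, hi)
  d <- pmax(1L, as.integer(round(stats::runif(
    length(kidx), params$delay_range[1], params$delay_range[2]))))
  data.frame(pre = pops$offset[proj$src[p_id]] + pre_l,
             post = pops$offset[proj$tgt[p_id]] + post_l,
             weight = w, delay = d, projection = p_id)
}

draw_noise_synapses <- function(noise, pops, params) {
  if (nrow(noise) == 0L)
    return(data.frame(pre = integer(), post = integer(), weight = numeric(),
                      delay = integer(), projection = integer()))
  n <- params$n_ensemble
  out <- vector("list", nrow(noise))
  for (s in seq_len(nrow(noise))) {
    m <- noise$size[s]
    keep <- which(stats::runif(m * n) <= params$p_conn)
    pre_l <- (keep - 1L) %/% n
    post_l <- (keep - 1L) %% n
    d <- pmax(1L, as.integer(round(stats::runif(
      length(keep), params$delay_range[1], params$delay_range[2]))))
    out[[s]] <- data.frame(
      pre = noise$offset[s] + pre_l,
      post = pops$offset[noise$target_pop[s]] + post_l,
      weight = noise$weight[s], delay = d, projection = NA_integer_)
  }
  do.call(rbind, out)
}

#' Bias a compiled network toward given clues
#'
#' Encodes pre-assigned variables (e.g. Sudoku clue digits) by exclusive
#' stimulation: for each clued variable, the stimulation (and dissipation)
#' noise sources of all \emph{other} value sub-populations are removed, so
#' only the clued value receives noise drive, and the clued sub-population
#' additionally receives a constant bias current.
#'
#' @param network a \code{"network_spec"}.
#' @param clues data.frame with columns \code{variable}, \code{value}
#'   (1-based domain index); defaults to the clues carried by the compiled
#'   CSP.
#' @return the modified \code{"network_spec"}.
#' @export
encode_clues <- function(network, clues = NULL) {
  stopifnot(inherits(network, "network_spec"))
  if (is.null(clues)) clues <- network$csp$clues
  if (is.null(clues) || nrow(clues) == 0L) return(network)
  dsz <- vapply(network$csp$domains, length, 1L)
  if (any(clues$variable < 1L | clues$variable > length(dsz)) ||
      any(clues$value < 1L | clues$value > dsz[clues$variable]))
    stop("clue value outside the variable's domain")
  pops <- network$populations
  clued_pop <- integer(0)
  off_pops <- integer(0)
  for (r in seq_len(nrow(clues))) {
    v <- clues$variable[r]
    vp <- pops$pop[pops$variable == v]
    cp <- vp[pops$domain[match(vp, pops$pop)] == clues$value[r]]
    clued_pop <- c(clued_pop, cp)
    off_pops <- c(off_pops, setdiff(vp, cp))
  }
  ns <- network$noise_sources
  if (nrow(ns) > 0L) {
    drop <- ns$target_pop %in% off_pops
    dropped_src <- ns$source[drop]
    if (length(dropped_src)) {
      dropped_off <- ns$offset[drop]
      dropped_end <- dropped_off + ns$size[drop]
      syn <- network$synapses
      pre_drop <- rep(FALSE, nrow(syn))
      for (k in seq_along(dropped_off))
        pre_drop <- pre_drop | (syn$pre >= dropped_off[k] &
                                syn$pre < dropped_end[k])
      network$synapses <- syn[!pre_drop, ]
      network$noise_sources <- ns[!drop, ]
      network$n_noise <- sum(network$noise_sources$size)
    }
  }
  network$currents[clued_pop] <-
    network$currents[clued_pop] + network$params$clue_bias
  network$clued <- clues
  network
}

#' Structural counts of a compiled network
#'
#' @param network a \code{"network_spec"}.
#' @return list: total neurons (principal + noise generators), principal and
#'   noise neuron counts, synapse count, number of principal populations,
#'   projection counts by class, domain sizes.
#' @export
network_summary <- function(network) {
  stopifnot(inherits(network, "network_spec"))
  dsz <- vapply(network$csp$domains, length, 1L)
  ns <- network$noise_sources
  list(n_neurons = network$n_principal +
         (if (nrow(ns)) sum(ns$size) else 0L),
       n_principal = network$n_principal,
       n_noise = if (nrow(ns)) sum(ns$size) else 0L,
       n_synapses = nrow(network$synapses),
       n_populations = nrow(network$populations),
       n_variables = network$csp$n_variables,
       domain_sizes = dsz,
       n_projections = c(table(factor(network$projections$class,
                                      levels = c("wta", "constraint")))),
       n_noise_sources = nrow(ns))
}

#' @export
print.network_spec <- function(x, ...) {
  s <- network_summary(x)
  cat(sprintf("Spiking network: %d neurons (%d principal in %d populations, %d noise), %d synapses\n",
              s$n_neurons, s$n_principal, s$n_populations, s$n_noise,
              s$n_synapses))
  cat(sprintf("  projections: %d winner-take-all, %d constraint; ensemble size %d\n",
              s$n_projections[["wta"]], s$n_projections[["constraint"]],
              x$params$n_ensemble))
  invisible(x)
}

#' Serialize a network description to structured text
#'
#' Writes populations, noise sources, projections, synapses and currents as
#' tab-separated sections for inspection or re-loading.
#'
#' @param network a \code{"network_spec"}.
#' @param path output file.
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "network_spec"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("format snncsp-network 1",
               paste("n_principal", network$n_principal),
               paste("seed", network$seed)), con)
  sec <- function(name, df) {
    writeLines(paste0("[", name, " ", nrow(df), "]"), con)
    if (nrow(df))
      utils::write.table(df, con, sep = "\t", row.names = FALSE,
                         quote = FALSE)
  }
  sec("populations", network$populations)
  sec("noise_sources", network$noise_sources)
  sec("projections", network$projections)
  sec("currents", data.frame(pop = seq_along(network$currents),
                             I = network$currents))
  sec("synapses", network$synapses)
  invisible(path)
}

#' @rdname write_network
#' @details \code{read_network} re-loads a serialized description. The
#'   source CSP and compiler parameters are not part of the format, so the
#'   returned object can be simulated and summarized but not re-compiled;
#'   population sizes stand in for the ensemble parameter.
#' @export
read_network <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "format snncsp-network"))
    stop("not an snncsp network file")
  n_principal <- as.integer(strsplit(lines[2], " ")[[1]][2])
  seed <- as.integer(strsplit(lines[3], " ")[[1]][2])
  heads <- grep("^\\[", lines)
  sections <- list()
  for (h in heads) {
    hd <- sub("^\\[(.*) (\\d+)\\]$", "\\1 \\2", lines[h])
    nm <- strsplit(hd, " ")[[1]]
    nr <- as.integer(nm[2])
    sections[[nm[1]]] <- if (nr > 0)
      utils::read.table(text = lines[(h + 1):(h + 1 + nr)], header = TRUE,
                        sep = "\t", stringsAsFactors = FALSE)
    else NULL
  }
  pops <- sections$populations
  ns <- sections$noise_sources
  if (is.null(ns))
    ns <- data.frame(target_pop = integer(), kind = character(),
                     size = integer(), rate_hz = numeric(),
                     weight = numeric(), start_ms = numeric(),
                     duration_ms = numeric(), source = integer(),
                     offset = integer())
  syn <- sections$synapses
  if (is.null(syn))
    syn <- data.frame(pre = integer(), post = integer(), weight = numeric(),
                      delay = integer(), projection = integer())
  # a minimal params stub: enough for simulation (n_ensemble for neuron ids)
  params <- compiler_params(n_ensemble = pops$size[1], stim = NULL,
                            diss = NULL, current = sections$currents$I[1])
  dsz <- as.vector(table(factor(pops$variable)))
  x <- csp(domains = lapply(dsz, function(k) as.character(seq_len(k))))
  structure(list(populations = pops, projections = sections$projections,
                 noise_sources = ns, synapses = syn,
                 currents = sections$currents$I,
                 n_principal = n_principal,
                 n_noise = if (nrow(ns)) sum(ns$size) else 0L,
                 params = params, csp = x, seed = seed),
            class = "network_spec")
}
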