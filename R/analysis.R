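#' Bin spikes into per-population counts
#'
#' Partitions the spike events into half-open time bins
#' \code{[k*w, (k+1)*w)} and counts events per (principal population, bin).
#'
#' @param spikes a \code{"spike_record"}.
#' @param bin_width bin width in ms (positive multiple of the 1 ms step);
#'   default 200 ms.
#' @return integer matrix populations x bins; every spike is counted exactly
#'   once.
#' @export
bin_spikes <- function(spikes, bin_width = 200) {
  stopifnot(inherits(spikes, "spike_record"))
  if (bin_width <= 0 || bin_width != round(bin_width))
    stop("'bin_width' must be a positive whole number of ms")
  n_pop <- nrow(spikes$populations)
  n_bin <- as.integer(ceiling(spikes$duration / bin_width))
  bin <- as.integer(spikes$time_ms %/% bin_width) + 1L
  counts <- tabulate((bin - 1L) * n_pop + spikes$pop, nbins = n_pop * n_bin)
  matrix(counts, nrow = n_pop, ncol = n_bin)
}

#' Decode network microstates from binned counts
#'
#' The winner-take-all reading of the network: in each bin, each variable is
#' assigned the domain whose sub-population spiked strictly most. Ties and
#' all-silent variables decode as undecided (\code{NA}) — satisfaction is
#' never granted on ambiguous activity.
#'
#' @param counts population x bin count matrix from [bin_spikes()].
#' @param x the compiled \code{"csp"} (defines the population layout).
#' @return integer matrix variables x bins of domain indices, \code{NA}
#'   where undecided.
#' @export
decode_states <- function(counts, x) {
  stopifnot(inherits(x, "csp"))
  dsz <- vapply(x$domains, length, 1L)
  if (nrow(counts) != sum(dsz))
    stop("'counts' must have one row per (variable, domain) population")
  n_bin <- ncol(counts)
  states <- matrix(NA_integer_, length(dsz), n_bin)
  off <- c(0L, cumsum(dsz))
  for (v in seq_along(dsz)) {
    sub <- counts[(off[v] + 1L):off[v + 1L], , drop = FALSE]
    mx <- apply(sub, 2, max)
    n_at_max <- colSums(sub == rep(mx, each = nrow(sub)))
    win <- max.col(t(sub), ties.method = "first")
    win[n_at_max != 1L | mx == 0L] <- NA_integer_
    states[v, ] <- win
  }
  states
}

state_keys <- function(states) {
  apply(states, 2, function(col) paste(ifelse(is.na(col), "?", col),
                                       collapse = ","))
}

#' Shannon entropy of the visited microstates
#'
#' \eqn{S(t) = -\sum_i p_i \log_2 p_i} in bits, where \eqn{p_i} is the
#' empirical frequency of each distinct decoded microstate over the trailing
#' window of bins ending at \code{t}. The default window is the full history
#' (cumulative estimate); a finite window gives a sliding estimate.
#'
#' @param states variables x bins matrix from [decode_states()].
#' @param window trailing window length in bins (\code{Inf} = cumulative).
#' @return numeric vector of entropies, one per bin; bounded by
#'   \code{log2(min(window, t))}.
#' @export
entropy_trace <- function(states, window = Inf) {
  if (window < 1) stop("'window' must be >= 1")
  keys <- state_keys(states)
  B <- length(keys)
  S <- numeric(B)
  for (t in seq_len(B)) {
    lo <- if (is.finite(window)) max(1L, t - as.integer(window) + 1L) else 1L
    p <- tabulate(factor(keys[lo:t]))
    p <- p / sum(p)
    S[t] <- -sum(p * log2(p))
  }
  S
}

#' Mean firing rate per neuron per bin
#'
#' Discrete estimator of the network activity
#' \eqn{A(t) = N^{-1} \sum_j \sum_f \delta(t - t_j^f)}: total spikes in the
#' bin divided by (number of neurons x bin width).
#'
#' @param spikes a \code{"spike_record"}.
#' @param n_neurons number of neurons to normalize by (defaults to the
#'   record's principal-neuron count).
#' @param bin_width bin width, ms.
#' @return numeric vector, Hz per bin.
#' @export
activity_trace <- function(spikes, n_neurons = spikes$n_principal,
                           bin_width = 200) {
  stopifnot(inherits(spikes, "spike_record"), n_neurons >= 1)
  n_bin <- as.integer(ceiling(spikes$duration / bin_width))
  tot <- tabulate(as.integer(spikes$time_ms %/% bin_width) + 1L,
                  nbins = n_bin)
  tot / (n_neurons * bin_width / 1000)
}

#' Cumulative count of distinct visited states
#'
#' \eqn{\Omega(t)} = number of distinct decoded microstates seen up to bin
#' \code{t}, with per-bin flags for newly visited states, revisits and
#' bin-to-bin state changes.
#'
#' @param states variables x bins matrix from [decode_states()].
#' @return list: \code{omega} (non-decreasing integer vector), \code{new}
#'   (state first seen in this bin), \code{changed} (state differs from the
#'   previous bin), \code{revisit} (changed into a previously seen state).
#' @export
states_count <- function(states) {
  keys <- state_keys(states)
  new <- !duplicated(keys)
  changed <- c(FALSE, keys[-1] != keys[-length(keys)])
  list(omega = cumsum(new), new = new, changed = changed,
       revisit = changed & !new)
}

#' Per-bin decoded trace of a simulation
#'
#' Bins a spike record, decodes the per-variable winner-take-all states and
#' annotates every bin with the entropy, mean firing rate, cumulative
#' distinct-state count, satisfaction flag (the decoded assignment is
#' complete and consistent) and state-change flags.
#'
#' @param spikes a \code{"spike_record"}.
#' @param x the \code{"csp"} the network was compiled from.
#' @param bin_width bin width, ms.
#' @param entropy_window window for [entropy_trace()].
#' @return object of class \code{"state_trace"}: a per-bin data.frame
#'   (\code{$table}) plus the decoded state matrix (\code{$states}).
#' @export
state_trace <- function(spikes, x, bin_width = 200, entropy_window = Inf) {
  counts <- bin_spikes(spikes, bin_width)
  states <- decode_states(counts, x)
  B <- ncol(states)
  sat <- vapply(seq_len(B), function(b)
    check_assignment(x, states[, b])$satisfied, logical(1))
  sc <- states_count(states)
  tab <- data.frame(bin = seq_len(B), t_start = (seq_len(B) - 1) * bin_width,
                    entropy = entropy_trace(states, entropy_window),
                    rate_hz = activity_trace(spikes, bin_width = bin_width),
                    omega = sc$omega, satisfied = sat,
                    changed = sc$changed, new_state = sc$new)
  structure(list(table = tab, states = states, bin_width = bin_width,
                 counts = counts, csp = x),
            class = "state_trace")
}

#' @export
print.state_trace <- function(x, ...) {
  tb <- x$table
  cat(sprintf("State trace: %d bins of %d ms; %d distinct states; %d satisfying bins\n",
              nrow(tb), x$bin_width, max(tb$omega), sum(tb$satisfied)))
  invisible(x)
}

#' Export a state trace as a tab-separated table
#'
#' @param x a \code{"state_trace"}.
#' @param path output file.
#' @export
write_state_trace <- function(x, path) {
  stopifnot(inherits(x, "state_trace"))
  utils::write.table(x$table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Final decoded assignment from pooled bins
#'
#' Decodes the network's final configuration from the spike counts summed
#' over the last \code{pool_bins} bins instead of a single bin. Pooling over
#' a longer window removes decode ties on marginally driven variables (e.g.
#' balanced "free" spins in a frustrated quench) while leaving genuinely
#' ambiguous variables undecided.
#'
#' @param trace a \code{"state_trace"}.
#' @param pool_bins number of trailing bins to pool (default 5, i.e. 1 s at
#'   the default 200 ms bin).
#' @return integer assignment vector (\code{NA} = still undecided).
#' @export
final_assignment <- function(trace, pool_bins = 5) {
  stopifnot(inherits(trace, "state_trace"))
  B <- ncol(trace$counts)
  pool_bins <- min(pool_bins, B)
  pooled <- rowSums(trace$counts[, (B - pool_bins + 1L):B, drop = FALSE])
  decode_states(matrix(pooled, ncol = 1), trace$csp)[, 1]
}

#' Convergence time of a run
#'
#' \code{mode = "first"} gives the start time of the earliest satisfying
#' bin. \code{mode = "stable"} gives the start time of the earliest
#' satisfying bin from which every later bin also satisfies — the network may
#' keep hopping between distinct solutions, but never back to violation.
#'
#' @param trace a \code{"state_trace"}.
#' @param mode \code{"first"} or \code{"stable"}.
#' @return time in ms, or \code{NA} if the run never (stably) satisfied.
#' @export
solve_time <- function(trace, mode = c("first", "stable")) {
  stopifnot(inherits(trace, "state_trace"))
  mode <- match.arg(mode)
  sat <- trace$table$satisfied
  if (!any(sat)) return(NA_real_)
  w <- trace$bin_width
  if (mode == "first") return((which(sat)[1] - 1) * w)
  if (!sat[length(sat)]) return(NA_real_)
  lastF <- max(c(0L, which(!sat)))
  (lastF) * w  # first bin of the all-satisfying suffix, 0-based start time
}

#' Convergence statistics over repeated runs
#'
#' Summarizes per-run solve times: success ratio \eqn{\xi} (successes over
#' all runs) and, over the successful runs only, the mean \eqn{\mu},
#' standard deviation \eqn{\sigma}, adjusted Fisher-Pearson sample skewness
#' \eqn{\gamma_1} and best time \eqn{t_{min}}. Moments that need more
#' successes than available are reported as \code{NA}, never fabricated.
#'
#' @param times numeric vector of per-run solve times (any consistent unit);
#'   \code{NA} marks a run that did not converge.
#' @return object of class \code{"run_stats"}.
#' @export
experiment_stats <- function(times) {
  if (length(times) < 1L) stop("need at least one run")
  succ <- times[!is.na(times)]
  n <- length(succ)
  g1 <- if (n >= 3L && stats::sd(succ) > 0) {
    m2 <- mean((succ - mean(succ))^2)
    m3 <- mean((succ - mean(succ))^3)
    (m3 / m2^1.5) * sqrt(n * (n - 1)) / (n - 2)
  } else NA_real_
  structure(list(n_runs = length(times), n_success = n,
                 xi = n / length(times),
                 mu = if (n >= 1L) mean(succ) else NA_real_,
                 sigma = if (n >= 2L) stats::sd(succ) else NA_real_,
                 skewness = g1,
                 t_min = if (n >= 1L) min(succ) else NA_real_,
                 times = times),
            class = "run_stats")
}

#' @export
print.run_stats <- function(x, ...) {
  cat(sprintf("Runs: %d, successes: %d (xi = %.2f)\n",
              x$n_runs, x$n_success, x$xi))
  cat(sprintf("  mu = %s, sigma = %s, gamma1 = %s, t_min = %s\n",
              format(x$mu, digits = 4), format(x$sigma, digits = 4),
              format(x$skewness, digits = 4), format(x$t_min, digits = 4)))
  invisible(x)
}

#' Write run statistics as structured text
#'
#' @param x a \code{"run_stats"}.
#' @param path output file.
#' @export
write_run_stats <- function(x, path) {
  stopifnot(inherits(x, "run_stats"))
  lines <- c("format snncsp-runstats 1",
             paste("n_runs", x$n_runs), paste("n_success", x$n_success),
             paste("xi", x$xi), paste("mu", x$mu), paste("sigma", x$sigma),
             paste("skewness", x$skewness), paste("t_min", x$t_min),
             paste("times", paste(x$times, collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

#' Entropy / rate / states-count panels of a state trace
#'
#' Mirrors the standard three-panel view of a stochastic search: entropy
#' colored by state dynamics (red = state changed since the previous bin,
#' green = unchanged, blue overlay = constraints satisfied), mean firing
#' rate, and cumulative visited-state count (black = new state, yellow =
#' revisit).
#'
#' @param x a \code{"state_trace"}.
#' @param ... ignored.
#' @export
plot.state_trace <- function(x, ...) {
  tb <- x$table
  t_s <- (tb$t_start + x$bin_width / 2) / 1000
  op <- graphics::par(mfrow = c(3, 1), mar = c(2.5, 4, 1, 1), mgp = c(2, .6, 0))
  on.exit(graphics::par(op))
  col <- ifelse(tb$changed, "red", "darkgreen")
  graphics::plot(t_s, tb$entropy, type = "h", col = col,
                 xlab = "", ylab = "entropy S (bits)")
  if (any(tb$satisfied))
    graphics::points(t_s[tb$satisfied], tb$entropy[tb$satisfied],
                     col = "blue", pch = 16, cex = .6)
  graphics::plot(t_s, tb$rate_hz, type = "l", xlab = "",
                 ylab = expression(nu ~ "(Hz)"))
  graphics::plot(t_s, tb$omega, type = "s", xlab = "time (s)",
                 ylab = expression(Omega ~ "(states)"))
  graphics::points(t_s[tb$new_state], tb$omega[tb$new_state], pch = 16,
                   cex = .5)
  rv <- tb$changed & !tb$new_state
  if (any(rv))
    graphics::points(t_s[rv], tb$omega[rv], pch = 16, cex = .5,
                     col = "goldenrod")
  invisible(x)
}

#' Histogram of convergence times
#'
#' @param x a \code{"run_stats"}.
#' @param main title.
#' @param unit axis label for the time unit.
#' @param ... passed to [graphics::hist()].
#' @export
plot.run_stats <- function(x, main = "Convergence times", unit = "time",
                           ...) {
  succ <- x$times[!is.na(x$times)]
  if (!length(succ)) {
    graphics::plot.new()
    graphics::title(main = paste(main, "(no successful runs)"))
    return(invisible(x))
  }
  graphics::hist(succ, main = main, xlab = unit, col = "grey80", ...)
  lab <- sprintf("mu = %.3g  sigma = %.3g  gamma1 = %.3g  xi = %.2f  t_min = %.3g",
                 x$mu, x$sigma, x$skewness, x$xi, x$t_min)
  graphics::mtext(lab, side = 3, line = -1.2, cex = .8)
  invisible(x)
}
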