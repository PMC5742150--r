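# build a spike_record by hand for a CSP with the given domain sizes
fake_record <- function(times, pops, dsz, duration, n = 1L) {
  populations <- data.frame(pop = seq_len(sum(dsz)),
                            variable = rep(seq_along(dsz), dsz),
                            domain = unlist(lapply(dsz, seq_len)),
                            size = n)
  populations$offset <- (populations$pop - 1L) * n
  structure(list(time_ms = times, neuron = pops, pop = pops,
                 duration = duration, n_principal = sum(dsz) * n,
                 populations = populations, vm = NULL, dt = 1),
            class = "spike_record")
}

test_that("spike binning partitions events into half-open 200 ms bins", {
  dsz <- c(2, 2)
  empty <- fake_record(numeric(0), integer(0), dsz, 600)
  expect_equal(bin_spikes(empty), matrix(0L, 4, 3))

  one <- fake_record(250, 3L, dsz, 600)
  b <- bin_spikes(one)
  expect_equal(b[3, 2], 1L)
  expect_equal(sum(b), 1L)

  edge <- fake_record(c(0, 199, 200, 399, 400), rep(1L, 5), dsz, 600)
  expect_equal(bin_spikes(edge)[1, ], c(2L, 2L, 1L))

  set.seed(1)
  t10 <- sort(runif(10, 0, 599))
  r10 <- fake_record(t10, sample(1:4, 10, TRUE), dsz, 600)
  expect_equal(sum(bin_spikes(r10)), 10L)
})

test_that("state decoding takes strict winners and leaves ties undecided", {
  x <- csp(domains = list(as.character(1:3)))
  expect_equal(decode_states(matrix(c(10, 2, 1), 3, 1), x)[1, 1], 1L)
  expect_true(is.na(decode_states(matrix(c(5, 5, 0), 3, 1), x)[1, 1]))
  expect_true(is.na(decode_states(matrix(0, 3, 1), x)[1, 1]))
  two <- csp(domains = rep(list(c("a", "b")), 2))
  st <- decode_states(matrix(c(1, 3, 2, 2), 4, 1), two)
  expect_equal(st[1, 1], 2L)
  expect_true(is.na(st[2, 1]))
})

test_that("entropy is zero on a constant trace and log2 K on uniform traces", {
  const <- matrix(1L, 2, 6)
  expect_equal(entropy_trace(const), rep(0, 6))

  four <- matrix(c(1, 1, 1, 2, 2, 1, 2, 2), nrow = 2)  # 4 distinct states
  expect_equal(entropy_trace(four)[4], 2)

  for (K in c(2, 4, 8)) {
    states <- matrix(rep(seq_len(K), each = 1), nrow = 1)
    expect_equal(entropy_trace(states)[K], log2(K))
  }

  # trailing-window estimate: window of 2 over alternating states -> 1 bit
  alt <- matrix(rep(c(1L, 2L), 5), nrow = 1)
  expect_equal(entropy_trace(alt, window = 2)[-1], rep(1, 9))
})

test_that("entropy is bounded by log2 of the window on random traces", {
  set.seed(5)
  for (rep in 1:5) {
    states <- matrix(sample(1:3, 40, TRUE), nrow = 2)
    S <- entropy_trace(states)
    expect_true(all(S >= 0))
    expect_true(all(S <= log2(seq_len(20))))
    Sw <- entropy_trace(states, window = 4)
    expect_true(all(Sw <= 2))
    expect_equal(S[1], 0)
  }
})

test_that("activity is total spikes over neurons x bin width", {
  r <- fake_record(rep(100, 2000), sample(1:4, 2000, TRUE), c(2, 2), 200,
                   n = 25L)
  expect_equal(activity_trace(r), 100)  # 2000 / (100 * 0.2 s)
  silent <- fake_record(numeric(0), integer(0), c(2, 2), 400, n = 25L)
  expect_equal(activity_trace(silent), c(0, 0))
  expect_equal(activity_trace(r, n_neurons = 200), 50)
})

test_that("states_count tracks distinct states, revisits and changes", {
  # states A, A, B, A
  st <- matrix(c(1L, 1L, 2L, 1L), nrow = 1)
  sc <- states_count(st)
  expect_equal(sc$omega, c(1, 1, 2, 2))
  expect_equal(sc$changed, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(sc$revisit, c(FALSE, FALSE, FALSE, TRUE))

  same <- matrix(1L, 2, 5)
  expect_equal(states_count(same)$omega, rep(1, 5))
  expect_false(any(states_count(same)$changed))

  dist <- matrix(1:6, nrow = 1)
  expect_equal(states_count(dist)$omega, 1:6)

  set.seed(3)
  rnd <- matrix(sample(1:2, 30, TRUE), nrow = 3)
  omega <- states_count(rnd)$omega
  expect_true(all(diff(omega) >= 0))
  expect_lte(max(omega), min(ncol(rnd), 2^3))
})

test_that("solve_time distinguishes first from stable convergence", {
  mk_trace <- function(sat) {
    structure(list(table = data.frame(bin = seq_along(sat),
                                      t_start = (seq_along(sat) - 1) * 200,
                                      satisfied = sat),
                   bin_width = 200), class = "state_trace")
  }
  ft <- mk_trace(c(FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(solve_time(ft, "first"), 400)
  expect_equal(solve_time(ft, "stable"), 400)

  blip <- mk_trace(c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(solve_time(blip, "first"), 200)
  expect_true(is.na(solve_time(blip, "stable")))

  never <- mk_trace(rep(FALSE, 4))
  expect_true(is.na(solve_time(never, "first")))
  expect_true(is.na(solve_time(never, "stable")))

  swap <- mk_trace(c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(solve_time(swap, "stable"), 200)
  allT <- mk_trace(rep(TRUE, 3))
  expect_equal(solve_time(allT, "stable"), 0)
})

test_that("run statistics match direct formula evaluation", {
  s <- experiment_stats(c(1, 2, 3, NA))
  expect_equal(s$xi, 0.75)
  expect_equal(s$mu, 2)
  expect_equal(s$t_min, 1)
  expect_equal(s$sigma, 1)

  fail <- experiment_stats(c(NA, NA))
  expect_equal(fail$xi, 0)
  expect_true(is.na(fail$mu) && is.na(fail$t_min))

  single <- experiment_stats(c(NA, 5))
  expect_equal(single$mu, 5)
  expect_true(is.na(single$sigma))
  expect_true(is.na(single$skewness))
  expect_equal(single$t_min, 5)

  # adjusted Fisher-Pearson skewness against a direct computation
  x <- c(1, 1, 2, 4, 9)
  n <- length(x)
  m2 <- mean((x - mean(x))^2); m3 <- mean((x - mean(x))^3)
  g1 <- (m3 / m2^1.5) * sqrt(n * (n - 1)) / (n - 2)
  expect_equal(experiment_stats(x)$skewness, g1)
  expect_gt(g1, 0)
})

test_that("state traces annotate satisfaction consistently with a direct constraint scan", {
  tri <- csp_from_graph_coloring(rbind(c(1, 2), c(2, 3), c(1, 3)), k = 3)
  # hand-built activity: bin 1 coloring (1,2,3); bin 2 conflict (1,1,3);
  # bin 3 variable 2 silent
  times <- c(rep(10, 5), rep(50, 4), rep(80, 3),      # pops 1, 5, 9
             rep(210, 5), rep(250, 4), rep(280, 3),   # pops 1, 2, 9
             rep(410, 5), rep(480, 3))                # pops 1, 9
  pops <- c(rep(1L, 5), rep(5L, 4), rep(9L, 3),
            rep(1L, 5), rep(4L, 4), rep(9L, 3),
            rep(1L, 5), rep(9L, 3))
  rec <- fake_record(times, pops, rep(3, 3), 600)
  tr <- state_trace(rec, tri)
  expect_equal(tr$table$satisfied, c(TRUE, FALSE, FALSE))
  expect_equal(tr$states[, 1], c(1L, 2L, 3L))
  expect_equal(tr$states[, 2], c(1L, 1L, 3L))
  expect_true(is.na(tr$states[2, 3]))

  # independent per-bin re-check: all pairs of variables must differ
  for (b in 1:3) {
    a <- tr$states[, b]
    ok <- !anyNA(a) && a[1] != a[2] && a[2] != a[3] && a[1] != a[3]
    expect_equal(tr$table$satisfied[b], ok)
  }

  expect_equal(max(tr$table$omega), 3)
  expect_equal(solve_time(tr, "first"), 0)
  expect_true(is.na(solve_time(tr, "stable")))
})

test_that("final_assignment pools trailing bins to break marginal ties", {
  x <- csp(domains = list(c("a", "b")))
  # bin counts: pop1 then pop2 per bin; last bin tied, pooled decides
  counts <- matrix(c(3, 1, 3, 1, 2, 2), nrow = 2)
  tr <- structure(list(table = NULL, states = decode_states(counts, x),
                       bin_width = 200, counts = counts, csp = x),
                  class = "state_trace")
  expect_true(is.na(tr$states[1, 3]))
  expect_equal(final_assignment(tr, pool_bins = 3), 1L)
  expect_true(is.na(final_assignment(tr, pool_bins = 1)))
})
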