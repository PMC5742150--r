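test_that("graph coloring CSPs have one variable per vertex and one negative constraint per edge", {
  tri <- csp_from_graph_coloring(rbind(c(1, 2), c(2, 3), c(1, 3)), k = 3)
  expect_equal(tri$n_variables, 3L)
  expect_equal(nrow(tri$constraints), 3L)
  expect_true(all(tri$constraints$sign == -1))
  expect_equal(length(brute_force_solve(tri)), 6L)  # the 3! proper colorings

  k4 <- csp_from_graph_coloring(t(combn(4, 2)), k = 3)
  expect_equal(length(brute_force_solve(k4)), 0L)   # K4 is not 3-colorable

  single <- csp_from_graph_coloring(matrix(integer(), ncol = 2), k = 1,
                                    vertices = "a")
  expect_equal(length(brute_force_solve(single)), 1L)

  expect_error(csp_from_graph_coloring(rbind(c(1, 1)), k = 2), "self-loop")
  # duplicate edges collapse to one constraint
  dup <- csp_from_graph_coloring(rbind(c(1, 2), c(2, 1), c(1, 2)), k = 2)
  expect_equal(nrow(dup$constraints), 1L)
})

test_that("Sudoku CSPs carry 81 nine-valued variables and 810 distinct pair constraints", {
  x <- csp_from_sudoku(strrep("0", 81))
  expect_equal(x$n_variables, 81L)
  expect_true(all(vapply(x$domains, length, 1L) == 9L))
  expect_equal(nrow(x$constraints), 810L)
  expect_null(x$clues)

  # independently recount: row + column + box pairs, deduplicated
  pair_set <- new.env()
  add <- function(a, b) assign(paste(min(a, b), max(a, b)), TRUE, pair_set)
  cell <- function(r, c) (r - 1) * 9 + c
  for (r in 1:9) for (c1 in 1:8) for (c2 in (c1 + 1):9)
    add(cell(r, c1), cell(r, c2))
  for (c in 1:9) for (r1 in 1:8) for (r2 in (r1 + 1):9)
    add(cell(r1, c), cell(r2, c))
  for (br in 0:2) for (bc in 0:2) {
    cells <- as.vector(outer(br * 3 + 1:3, bc * 3 + 1:3,
                             function(r, c) cell(r, c)))
    for (i in 1:8) for (j in (i + 1):9) add(cells[i], cells[j])
  }
  expect_equal(nrow(x$constraints), length(ls(pair_set)))

  withclues <- csp_from_sudoku(paste0("53..7....6..195....98....6.8...6...34..8.3..17...2...6.6....28....419..5....8..79"))
  expect_equal(nrow(withclues$clues), 30L)
  expect_error(csp_from_sudoku(paste0("55", strrep("0", 79))), "inconsistent")
  expect_error(csp_from_sudoku("123"), "81")
})

test_that("check_assignment separates violated from undetermined constraints", {
  tri <- csp_from_graph_coloring(rbind(c(1, 2), c(2, 3), c(1, 3)), k = 3)
  expect_true(check_assignment(tri, c(1, 2, 3))$satisfied)
  expect_length(check_assignment(tri, c(1, 2, 3))$violated, 0)

  bad <- check_assignment(tri, c(1, 1, 2))
  expect_false(bad$satisfied)
  expect_length(bad$violated, 1)

  part <- check_assignment(tri, c(1, NA, 2))
  expect_false(part$satisfied)
  expect_length(part$violated, 0)
  expect_length(part$undetermined, 2)

  expect_error(check_assignment(tri, c(1, 2, 9)), "domain")

  # a full valid Sudoku grid satisfies the Sudoku CSP, per an independent
  # row/column/box checker
  grid <- "483957261915362748267184953198475632652893174374621589531246897846719325729538416"
  digits <- as.integer(strsplit(grid, "")[[1]])
  expect_true(ref_sudoku_ok(digits))
  sud <- csp_from_sudoku(strrep("0", 81))
  expect_true(check_assignment(sud, digits)$satisfied)
  # breaking one cell breaks satisfaction
  digits2 <- digits; digits2[1] <- digits[2]
  expect_false(check_assignment(sud, digits2)$satisfied)
})

test_that("brute_force_solve enumerates exhaustively in lexicographic order", {
  free <- csp(domains = list(as.character(1:4)))
  expect_equal(length(brute_force_solve(free)), 4L)

  two <- csp(domains = rep(list(c("a", "b")), 2),
             constraints = data.frame(i = 1, j = 2, sign = -1))
  sols <- brute_force_solve(two)
  expect_equal(sols, list(c(1L, 2L), c(2L, 1L)))

  big <- csp(domains = rep(list(as.character(1:10)), 8))
  expect_error(brute_force_solve(big, cap = 1e6), "cap")
})

test_that("spin lattices have the exact open-boundary bond structure", {
  chain <- make_spin_lattice(10, p_AF = 1, seed = 1)
  expect_equal(nrow(chain$bonds), 9L)
  expect_true(all(chain$bonds$J == -1))

  cube <- make_spin_lattice(c(10, 10, 10), p_AF = 0.5, seed = 2)
  expect_equal(cube$n_sites, 1000L)
  expect_equal(nrow(cube$bonds), 3L * 9L * 10L * 10L)  # 2700 grid bonds

  fm <- make_spin_lattice(c(4, 4), p_AF = 0, U = 2, seed = 3)
  expect_equal(nrow(fm$bonds), 24L)                    # 2 * L * (L - 1)
  expect_true(all(fm$bonds$J == 2))

  expect_error(make_spin_lattice(10, p_AF = 1.5), "p_AF")

  expect_identical(make_spin_lattice(c(5, 5), 0.5, seed = 7),
                   make_spin_lattice(c(5, 5), 0.5, seed = 7))
  l1 <- make_spin_lattice(c(6, 6), 0.5, seed = 1)
  l2 <- make_spin_lattice(c(6, 6), 0.5, seed = 2)
  expect_false(identical(l1$bonds$J, l2$bonds$J))
})

test_that("ising_energy matches hand-computed values and rejects bad spins", {
  chain4 <- spin_system(4, data.frame(i = 1:3, j = 2:4, J = 1))
  expect_equal(ising_energy(chain4, c(1, 1, 1, 1)), -3)

  one <- spin_system(1, data.frame(i = integer(), j = integer(),
                                   J = numeric()), h = 1)
  expect_equal(ising_energy(one, 1), -1)

  tri_af <- make_spin_ring(3, antiferromagnetic = TRUE)
  configs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 3)))
  energies <- apply(configs, 1, function(s) ising_energy(tri_af, s))
  expect_equal(min(energies), -1)  # frustrated: at best 2 of 3 bonds

  expect_error(ising_energy(chain4, c(1, 0, 1, 1)), "\\+1 or -1")
})

test_that("spin systems map to CSPs whose violations count frustrated bonds", {
  ring4 <- make_spin_ring(4, antiferromagnetic = TRUE)
  x4 <- csp_from_spin_system(ring4)
  sols <- brute_force_solve(x4)
  expect_equal(length(sols), 2L)  # the two alternating assignments
  for (s in sols) {
    spins <- spins_from_assignment(s)
    expect_true(all(abs(diff(spins)) == 2))
  }

  tri <- csp_from_spin_system(make_spin_ring(3, antiferromagnetic = TRUE))
  expect_equal(length(brute_force_solve(tri)), 0L)
  worst <- sapply(brute_force_solve(csp(domains = tri$domains)), function(a)
    length(check_assignment(tri, a)$violated))
  expect_equal(min(worst), 1L)    # at most 2 of 3 constraints satisfiable

  fm <- csp_from_spin_system(make_spin_lattice(5, p_AF = 0, seed = 1))
  expect_true(check_assignment(fm, rep(1L, 5))$satisfied)  # all-up

  # violated constraints == frustrated bonds, for random configs
  sys <- make_spin_lattice(c(4, 4), p_AF = 0.5, seed = 11)
  x <- csp_from_spin_system(sys)
  set.seed(42)
  for (rep in 1:20) {
    spins <- sample(c(-1, 1), 16, replace = TRUE)
    a <- ifelse(spins == 1, 1L, 2L)
    expect_equal(length(check_assignment(x, a)$violated),
                 ref_frustrated(sys, spins))
  }
})

test_that("lower Ising energy is exactly more satisfied constraints", {
  # E = U * (violated - satisfied) on |J| = U systems, so the exhaustive
  # minimum sits at the maximum satisfied-constraint count
  for (seed in 1:3) {
    sys <- make_spin_lattice(c(4, 4), p_AF = 0.5, U = 1, seed = seed)
    x <- csp_from_spin_system(sys)
    m <- nrow(sys$bonds)
    configs <- as.matrix(expand.grid(rep(list(c(1L, 2L)), 16)))
    E <- apply(configs, 1, function(a)
      ising_energy(sys, spins_from_assignment(a)))
    nsat <- apply(configs, 1, function(a)
      m - length(check_assignment(x, a)$violated))
    expect_equal(E, 1 * (m - 2 * nsat))
    expect_equal(which.min(E), which.max(nsat))
  }
})

test_that("check_assignment agrees with brute-force membership on random CSPs", {
  for (seed in 1:8) {
    x <- random_csp(seed)
    sols <- brute_force_solve(x)
    keys <- vapply(sols, paste, "", collapse = ",")
    all_assign <- brute_force_solve(csp(domains = x$domains))
    for (a in all_assign) {
      expect_equal(check_assignment(x, a)$satisfied,
                   paste(a, collapse = ",") %in% keys)
    }
  }
})

test_that("CSP constructor enforces its invariants", {
  expect_error(csp(list()), "non-empty")
  expect_error(csp(list(character(0))), "non-empty")
  expect_error(csp(list(c("a"), c("b")),
                   data.frame(i = 1, j = 1, sign = -1)), "distinct")
  expect_error(csp(list(c("a"), c("b")),
                   data.frame(i = 1, j = 3, sign = -1)), "invalid")
  expect_error(csp(list(c("a"), c("b")),
                   data.frame(i = c(1, 2), j = c(2, 1), sign = -1)),
               "duplicate")
  expect_error(csp(list(c("a"), c("b")),
                   data.frame(i = 1, j = 2, sign = 0.5)), "sign")
})
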