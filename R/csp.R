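#' Construct a binary constraint satisfaction problem
#'
#' A CSP is a tuple of variables, per-variable value domains and binary
#' constraints between pairs of variables. Constraints are signed: a
#' \emph{negative} constraint forbids the two variables from taking equal
#' values (e.g. adjacent map regions must differ in color), a \emph{positive}
#' constraint requires them to be equal (e.g. ferromagnetically coupled
#' spins).
#'
#' @param domains list of character vectors, one per variable, each giving
#'   the ordered value labels of that variable's domain. All domains must be
#'   non-empty.
#' @param constraints data.frame with integer columns \code{i}, \code{j}
#'   (1-based variable indices, distinct within a row) and numeric column
#'   \code{sign} (\code{-1} for negative, \code{+1} for positive). An
#'   optional character column \code{strength} tags a weight-range class for
#'   the compiler. Duplicate (unordered scope, sign) pairs are rejected.
#' @param labels optional character vector of variable names.
#' @param clues optional data.frame with columns \code{variable} and
#'   \code{value} (1-based domain index) carrying pre-assigned variables;
#'   used by the network compiler to bias stimulation.
#' @param meta optional list of free-form metadata.
#'
#' @return An object of class \code{"csp"}: a list with elements
#'   \code{n_variables}, \code{domains}, \code{constraints}, \code{labels},
#'   \code{clues}, \code{meta}.
#' @seealso [csp_from_graph_coloring()], [csp_from_sudoku()],
#'   [csp_from_spin_system()], [check_assignment()], [brute_force_solve()]
#' @export
csp <- function(domains, constraints = NULL, labels = NULL, clues = NULL,
                meta = list()) {
  if (!is.list(domains) || length(domains) == 0L)
    stop("'domains' must be a non-empty list of value-label vectors")
  domains <- lapply(domains, as.character)
  if (any(vapply(domains, length, 1L) == 0L))
    stop("every domain must be non-empty")
  n <- length(domains)

  if (is.null(constraints)) {
    constraints <- data.frame(i = integer(), j = integer(), sign = numeric(),
                              strength = character())
  }
  constraints <- as.data.frame(constraints)
  if (!all(c("i", "j", "sign") %in% names(constraints)))
    stop("'constraints' needs columns i, j, sign")
  if (!"strength" %in% names(constraints))
    constraints$strength <- rep(NA_character_, nrow(constraints))
  constraints$i <- as.integer(constraints$i)
  constraints$j <- as.integer(constraints$j)
  constraints$sign <- as.numeric(constraints$sign)
  if (nrow(constraints) > 0L) {
    if (any(constraints$i < 1L | constraints$i > n |
            constraints$j < 1L | constraints$j > n))
      stop("constraint scope references an invalid variable index")
    if (any(constraints$i == constraints$j))
      stop("constraint scope indices must be distinct (no self-loops)")
    if (!all(constraints$sign %in% c(-1, 1)))
      stop("constraint sign must be -1 (values differ) or +1 (values equal)")
    key <- paste(pmin(constraints$i, constraints$j),
                 pmax(constraints$i, constraints$j), constraints$sign)
    if (anyDuplicated(key))
      stop("duplicate (scope, relation) constraint pairs are not allowed")
  }

  if (is.null(labels)) labels <- paste0("x", seq_len(n))
  if (length(labels) != n) stop("'labels' must have one name per variable")

  if (!is.null(clues)) {
    clues <- as.data.frame(clues)
    if (!all(c("variable", "value") %in% names(clues)))
      stop("'clues' needs columns variable, value")
    clues$variable <- as.integer(clues$variable)
    clues$value <- as.integer(clues$value)
    bad <- clues$variable < 1L | clues$variable > n |
      clues$value < 1L |
      clues$value > vapply(domains[clues$variable], length, 1L)
    if (any(bad)) stop("clue refers to an invalid variable or domain value")
  }

  structure(list(n_variables = n, domains = domains,
                 constraints = constraints, labels = as.character(labels),
                 clues = clues, meta = meta),
            class = "csp")
}

#' @export
print.csp <- function(x, ...) {
  dsz <- vapply(x$domains, length, 1L)
  cat(sprintf("Binary CSP: %d variables, %d constraints (%d negative, %d positive)\n",
              x$n_variables, nrow(x$constraints),
              sum(x$constraints$sign < 0), sum(x$constraints$sign > 0)))
  cat(sprintf("  domain sizes: %s\n",
              if (length(unique(dsz)) == 1L) as.character(dsz[1])
              else paste0(min(dsz), "-", max(dsz))))
  if (!is.null(x$clues))
    cat(sprintf("  clues: %d pre-assigned variables\n", nrow(x$clues)))
  invisible(x)
}

#' Graph k-coloring as a CSP
#'
#' One variable per vertex with a k-value color domain, and one negative
#' (values-must-differ) constraint per undirected edge.
#'
#' @param edges two-column matrix or data.frame of edge endpoints. Endpoints
#'   may be integers or character vertex names; vertices are ordered by first
#'   appearance in the edge list.
#' @param k number of colors (>= 1).
#' @param vertices optional vector of vertex names, to include isolated
#'   vertices and fix ordering.
#' @return A \code{"csp"} object. Vertex names are kept as variable labels.
#' @examples
#' tri <- csp_from_graph_coloring(rbind(c(1, 2), c(2, 3), c(1, 3)), k = 3)
#' length(brute_force_solve(tri))  # the 3! = 6 proper colorings
#' @export
csp_from_graph_coloring <- function(edges, k, vertices = NULL) {
  if (!is.numeric(k) || length(k) != 1L || k < 1)
    stop("'k' must be a single color count >= 1")
  k <- as.integer(k)
  edges <- as.matrix(edges)
  if (length(edges) && ncol(edges) != 2L)
    stop("'edges' must have two columns")
  ev <- as.character(t(edges))
  verts <- unique(c(if (!is.null(vertices)) as.character(vertices), ev))
  if (length(verts) == 0L) stop("graph has no vertices")
  n <- length(verts)
  if (nrow(edges) > 0L) {
    u <- match(as.character(edges[, 1]), verts)
    v <- match(as.character(edges[, 2]), verts)
    if (any(u == v))
      stop("self-loop edge: a vertex cannot take a color different from itself")
    key <- paste(pmin(u, v), pmax(u, v))
    keep <- !duplicated(key)
    cons <- data.frame(i = u[keep], j = v[keep], sign = -1)
  } else {
    cons <- NULL
  }
  csp(domains = rep(list(as.character(seq_len(k) - 1L)), n),
      constraints = cons, labels = verts,
      meta = list(problem = "graph_coloring", k = k))
}

# row, column and 3x3-box peer pairs of the 81-cell grid, deduplicated
sudoku_constraint_pairs <- function() {
  cell <- function(r, c) (r - 1L) * 9L + c
  comb <- t(utils::combn(9L, 2L))
  rows <- do.call(rbind, lapply(1:9, function(r) cbind(cell(r, comb[, 1]), cell(r, comb[, 2]))))
  cols <- do.call(rbind, lapply(1:9, function(c) cbind(cell(comb[, 1], c), cell(comb[, 2], c))))
  boxes <- do.call(rbind, lapply(0:8, function(b) {
    br <- (b %/% 3L) * 3L
    bc <- (b %% 3L) * 3L
    cells <- as.vector(outer(1:3 + bc, (1:3 + br - 1L) * 9L, "+"))
    t(utils::combn(cells, 2L))
  }))
  all <- rbind(rows, cols, boxes)
  all <- cbind(pmin(all[, 1], all[, 2]), pmax(all[, 1], all[, 2]))
  unique(all)
}

#' Sudoku puzzle as a CSP
#'
#' 81 variables (cells, row-major) with 9-digit domains, and a negative
#' constraint between every pair of cells sharing a row, a column or a 3x3
#' box (810 distinct pairs). Clue digits are carried as metadata for the
#' network compiler.
#'
#' @param clues an 81-character string, row-major; digits \code{1}-\code{9}
#'   are clues, \code{0} or \code{.} mark blank cells.
#' @return A \code{"csp"} with 81 variables; \code{$clues} holds the given
#'   digits.
#' @export
csp_from_sudoku <- function(clues) {
  clues <- gsub("[[:space:]]", "", clues)
  if (nchar(clues) != 81L)
    stop("a Sudoku puzzle needs exactly 81 cells (got ", nchar(clues), ")")
  ch <- strsplit(clues, "")[[1]]
  if (!all(ch %in% c(".", "0", as.character(1:9))))
    stop("cells must be digits 1-9, or '0'/'.' for blanks")
  digit <- match(ch, as.character(1:9))  # blanks ('.' or '0') become NA

  pairs <- sudoku_constraint_pairs()
  cons <- data.frame(i = pairs[, 1], j = pairs[, 2], sign = -1)

  # reject puzzles whose clues already violate a uniqueness constraint
  di <- digit[pairs[, 1]]; dj <- digit[pairs[, 2]]
  clash <- !is.na(di) & !is.na(dj) & di == dj
  if (any(clash))
    stop("inconsistent clues: equal digits in a row, column or box")

  clued <- which(!is.na(digit))
  clue_df <- if (length(clued))
    data.frame(variable = clued, value = digit[clued]) else NULL
  lab <- paste0("r", rep(1:9, each = 9), "c", rep(1:9, times = 9))
  csp(domains = rep(list(as.character(1:9)), 81L), constraints = cons,
      labels = lab, clues = clue_df,
      meta = list(problem = "sudoku", clue_string = clues))
}

#' Check an assignment against a CSP
#'
#' An assignment gives each variable a 1-based domain index, with \code{NA}
#' marking undecided variables (e.g. silent network populations). It is
#' \emph{satisfied} only if complete (no \code{NA}) and consistent: every
#' negative constraint joins two differing values and every positive
#' constraint two equal values.
#'
#' @param x a \code{"csp"}.
#' @param assignment integer vector of length \code{n_variables}; \code{NA}
#'   marks an undecided variable.
#' @return list with \code{satisfied} (flag), \code{violated} (indices of
#'   decided-and-violated constraints) and \code{undetermined} (indices of
#'   constraints touching an undecided variable).
#' @export
check_assignment <- function(x, assignment) {
  stopifnot(inherits(x, "csp"))
  a <- as.integer(assignment)
  if (length(a) != x$n_variables)
    stop("assignment must have one entry per variable")
  dsz <- vapply(x$domains, length, 1L)
  dec <- !is.na(a)
  if (any(a[dec] < 1L | a[dec] > dsz[dec]))
    stop("assignment value outside the variable's domain")
  cons <- x$constraints
  if (nrow(cons) == 0L) {
    return(list(satisfied = all(dec), violated = integer(),
                undetermined = integer()))
  }
  ai <- a[cons$i]; aj <- a[cons$j]
  und <- which(is.na(ai) | is.na(aj))
  both <- !is.na(ai) & !is.na(aj)
  viol <- which(both & ((cons$sign < 0 & ai == aj) |
                        (cons$sign > 0 & ai != aj)))
  list(satisfied = all(dec) && length(viol) == 0L,
       violated = viol, undetermined = und)
}

#' Exhaustive enumeration of all satisfying assignments
#'
#' Exact brute-force oracle for small instances: enumerates the full
#' Cartesian product of the domains in lexicographic order (first variable
#' most significant) and keeps the consistent complete assignments.
#'
#' @param x a \code{"csp"}.
#' @param cap refuse to enumerate more than this many assignments.
#' @return list of satisfying assignments (integer vectors of domain
#'   indices), in lexicographic order.
#' @export
brute_force_solve <- function(x, cap = 1e6) {
  stopifnot(inherits(x, "csp"))
  dsz <- vapply(x$domains, length, 1L)
  total <- prod(as.numeric(dsz))
  if (total > cap)
    stop(sprintf("state space has %.3g assignments, above the cap of %.3g",
                 total, cap))
  n <- x$n_variables
  # expand.grid varies the first factor fastest; feed variables reversed so
  # rows come out in lexicographic order with variable 1 most significant
  grids <- lapply(rev(dsz), seq_len)
  g <- as.matrix(do.call(expand.grid, c(grids, KEEP.OUT.ATTRS = FALSE)))
  g <- g[, rev(seq_len(n)), drop = FALSE]
  cons <- x$constraints
  ok <- rep(TRUE, nrow(g))
  for (r in seq_len(nrow(cons))) {
    vi <- g[, cons$i[r]]; vj <- g[, cons$j[r]]
    ok <- ok & if (cons$sign[r] < 0) vi != vj else vi == vj
    if (!any(ok)) break
  }
  sol <- g[ok, , drop = FALSE]
  lapply(seq_len(nrow(sol)), function(r) as.integer(sol[r, ]))
}

#' Assignment as human-readable value labels
#'
#' @param x a \code{"csp"}.
#' @param assignment integer domain indices (NA = undecided).
#' @return character vector of value labels, \code{NA} where undecided.
#' @export
assignment_labels <- function(x, assignment) {
  stopifnot(inherits(x, "csp"))
  vapply(seq_len(x$n_variables), function(v) {
    if (is.na(assignment[v])) NA_character_ else x$domains[[v]][assignment[v]]
  }, character(1))
}
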