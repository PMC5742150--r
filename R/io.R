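#' Read a graph in DIMACS .col format
#'
#' Parses the standard DIMACS coloring format: comment lines start with
#' \code{c}, a header \code{p edge <n> <m>} gives vertex and edge counts, and
#' each \code{e <u> <v>} line is an undirected edge with 1-based endpoints.
#'
#' @param path file path.
#' @return list with \code{n_vertices} and a two-column integer \code{edges}
#'   matrix.
#' @export
read_dimacs_col <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  hdr <- grep("^p[[:space:]]", lines, value = TRUE)
  if (length(hdr) != 1L)
    stop("expected exactly one 'p edge <n> <m>' header line")
  hf <- strsplit(hdr, "[[:space:]]+")[[1]]
  if (length(hf) < 4L || hf[2] != "edge")
    stop("malformed DIMACS header: ", hdr)
  n <- as.integer(hf[3]); m <- as.integer(hf[4])
  el <- grep("^e[[:space:]]", lines, value = TRUE)
  parts <- strsplit(el, "[[:space:]]+")
  u <- as.integer(vapply(parts, `[`, "", 2))
  v <- as.integer(vapply(parts, `[`, "", 3))
  if (anyNA(u) || anyNA(v) || any(u < 1L) || any(v < 1L) ||
      any(u > n) || any(v > n))
    stop("edge endpoints must be 1-based vertex indices within the header count")
  if (length(u) != m)
    warning(sprintf("header declares %d edges but %d 'e' lines found", m,
                    length(u)))
  list(n_vertices = n, edges = cbind(u, v))
}

#' Read a Sudoku clue string from a file
#'
#' The file holds one 81-character row-major clue string (digits 1-9, blanks
#' as '0' or '.'); lines starting with '#' are comments and whitespace is
#' ignored.
#'
#' @param path file path.
#' @return the 81-character clue string.
#' @export
read_sudoku_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  s <- gsub("[[:space:]]", "", paste(lines, collapse = ""))
  if (nchar(s) != 81L)
    stop("expected 81 puzzle cells in ", path, " (got ", nchar(s), ")")
  s
}

fixture_registry <- function() {
  list(
    "triangle-k3"   = list(kind = "coloring", k = 3,
                           desc = "complete graph K3, 3 colors (satisfiable)"),
    "k4-k3"         = list(kind = "coloring", k = 3,
                           desc = "complete graph K4, 3 colors (unsatisfiable)"),
    "australia"     = list(kind = "coloring", file = "australia.col", k = 3,
                           desc = "Australian states/territories adjacency, 3 colors"),
    "canada"        = list(kind = "coloring", file = "canada.col", k = 3,
                           desc = "Canadian provinces/territories adjacency, 3 colors"),
    "world"         = list(kind = "coloring", file = "world-synthetic.col", k = 4,
                           desc = "synthetic 193-vertex planar graph standing in for the UN world border list, 4 colors"),
    "sudoku-easy"   = list(kind = "sudoku", file = "sudoku-easy-synthetic.txt",
                           desc = "easy Sudoku, 36 clues (synthetic, unique solution)"),
    "sudoku-hard"   = list(kind = "sudoku", file = "sudoku-hard-synthetic.txt",
                           desc = "hard Sudoku, 26 clues (synthetic, unique solution)"),
    "ai-escargot"   = list(kind = "sudoku", file = "ai-escargot.txt",
                           desc = "AI Escargot, 23 clues"),
    "af-ring-10"    = list(kind = "spin",
                           desc = "antiferromagnetic ring of 10 spins"),
    "lattice-2d"    = list(kind = "spin",
                           desc = "10x10 spin glass, p_AF = 0.5 (seed 2017)"),
    "lattice-3d-fm" = list(kind = "spin",
                           desc = "10x10x10 ferromagnetic lattice"),
    "lattice-3d-af" = list(kind = "spin",
                           desc = "10x10x10 antiferromagnetic lattice")
  )
}

#' List the bundled benchmark fixtures
#'
#' @return data.frame with fixture names, kinds and descriptions.
#' @export
list_fixtures <- function() {
  reg <- fixture_registry()
  data.frame(name = names(reg),
             kind = vapply(reg, `[[`, "", "kind"),
             description = vapply(reg, `[[`, "", "desc"),
             row.names = NULL)
}

#' Load a bundled problem instance
#'
#' Returns a ready-to-compile instance: a \code{"csp"} for the coloring and
#' Sudoku fixtures, a \code{"spin_system"} for the spin fixtures (convert
#' with [csp_from_spin_system()]). See [list_fixtures()] for the registry.
#'
#' @param name fixture name.
#' @return a \code{"csp"} or \code{"spin_system"}.
#' @export
load_fixture <- function(name) {
  reg <- fixture_registry()
  if (!name %in% names(reg))
    stop("unknown fixture '", name, "'; available: ",
         paste(names(reg), collapse = ", "))
  fx <- reg[[name]]
  path <- function(f) system.file("extdata", f, package = "snncsp",
                                  mustWork = TRUE)
  if (name == "triangle-k3")
    return(csp_from_graph_coloring(rbind(c(1, 2), c(2, 3), c(1, 3)), k = 3))
  if (name == "k4-k3")
    return(csp_from_graph_coloring(t(utils::combn(4L, 2L)), k = 3))
  if (name == "af-ring-10")
    return(make_spin_ring(10, antiferromagnetic = TRUE))
  if (name == "lattice-2d")
    return(make_spin_lattice(c(10, 10), p_AF = 0.5, seed = 2017L))
  if (name == "lattice-3d-fm")
    return(make_spin_lattice(c(10, 10, 10), p_AF = 0, seed = 2017L))
  if (name == "lattice-3d-af")
    return(make_spin_lattice(c(10, 10, 10), p_AF = 1, seed = 2017L))
  if (fx$kind == "coloring") {
    g <- read_dimacs_col(path(fx$file))
    out <- csp_from_graph_coloring(g$edges, k = fx$k,
                                   vertices = seq_len(g$n_vertices))
    out$meta$fixture <- name
    return(out)
  }
  out <- csp_from_sudoku(read_sudoku_file(path(fx$file)))
  out$meta$fixture <- name
  out
}

#' Serialize a CSP to a structured text file
#'
#' Plain-text round-trip format: a header, one \code{domain} line per
#' variable, one \code{constraint} line per constraint and optional
#' \code{clue} lines.
#'
#' @param x a \code{"csp"}.
#' @param path output file.
#' @export
write_csp <- function(x, path) {
  stopifnot(inherits(x, "csp"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("format snncsp-csp 1",
               paste("variables", x$n_variables)), con)
  for (v in seq_len(x$n_variables))
    writeLines(paste("domain", x$labels[v],
                     paste(x$domains[[v]], collapse = " ")), con)
  cc <- x$constraints
  if (nrow(cc))
    writeLines(paste("constraint", cc$i, cc$j, cc$sign), con)
  if (!is.null(x$clues))
    writeLines(paste("clue", x$clues$variable, x$clues$value), con)
  invisible(path)
}

#' @rdname write_csp
#' @export
read_csp <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "format snncsp-csp"))
    stop("not an snncsp CSP file")
  tok <- strsplit(lines, "[[:space:]]+")
  key <- vapply(tok, `[`, "", 1)
  dom <- tok[key == "domain"]
  labels <- vapply(dom, `[`, "", 2)
  domains <- lapply(dom, function(t) t[-(1:2)])
  cons <- tok[key == "constraint"]
  cdf <- if (length(cons))
    data.frame(i = as.integer(vapply(cons, `[`, "", 2)),
               j = as.integer(vapply(cons, `[`, "", 3)),
               sign = as.numeric(vapply(cons, `[`, "", 4))) else NULL
  cl <- tok[key == "clue"]
  cldf <- if (length(cl))
    data.frame(variable = as.integer(vapply(cl, `[`, "", 2)),
               value = as.integer(vapply(cl, `[`, "", 3))) else NULL
  csp(domains = domains, constraints = cdf, labels = labels, clues = cldf)
}

#' Serialize a spin system to text
#'
#' @param x a \code{"spin_system"}.
#' @param path output file.
#' @export
write_spin_system <- function(x, path) {
  stopifnot(inherits(x, "spin_system"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("format snncsp-spin 1",
               paste("shape", paste(x$shape, collapse = " ")),
               paste("h", x$h), paste("U", x$U), paste("p_AF", x$p_AF)), con)
  b <- x$bonds
  if (nrow(b)) writeLines(paste("bond", b$i, b$j, b$J), con)
  invisible(path)
}

#' @rdname write_spin_system
#' @export
read_spin_system <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "format snncsp-spin"))
    stop("not an snncsp spin-system file")
  tok <- strsplit(lines, "[[:space:]]+")
  key <- vapply(tok, `[`, "", 1)
  val <- function(k) tok[[which(key == k)[1]]][-1]
  bl <- tok[key == "bond"]
  bonds <- data.frame(i = as.integer(vapply(bl, `[`, "", 2)),
                      j = as.integer(vapply(bl, `[`, "", 3)),
                      J = as.numeric(vapply(bl, `[`, "", 4)))
  spin_system(as.integer(val("shape")), bonds,
              h = as.numeric(val("h")), U = as.numeric(val("U")),
              p_AF = as.numeric(val("p_AF")))
}
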