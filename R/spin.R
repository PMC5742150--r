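#' Construct an Ising spin system
#'
#' A set of binary spins \eqn{S_i \in \{+1,-1\}} on a lattice with
#' nearest-neighbor couplings \eqn{J_{ij} \in \{+U, -U\}} and a uniform
#' external field \eqn{h}. The energy of a configuration is the Ising
#' Hamiltonian \eqn{H = -\sum_{ij} J_{ij} S_i S_j - h \sum_i S_i}:
#' ferromagnetic bonds (\eqn{J > 0}) favor aligned neighbors, antiferromagnetic
#' bonds (\eqn{J < 0}) anti-aligned ones.
#'
#' @param shape integer vector of side lengths (1 to 3 dimensions). Sites are
#'   indexed linearly in R's column-major order.
#' @param bonds data.frame with columns \code{i}, \code{j} (site indices) and
#'   \code{J} (coupling, \code{+U} or \code{-U}).
#' @param h external field (scalar).
#' @param U coupling magnitude; every \code{|J|} must equal \code{U}.
#' @param p_AF the antiferromagnetic-bond probability the bonds were drawn
#'   with (metadata; \code{NA} for hand-built systems).
#' @return object of class \code{"spin_system"}.
#' @seealso [make_spin_lattice()], [ising_energy()], [csp_from_spin_system()]
#' @export
spin_system <- function(shape, bonds, h = 0, U = 1, p_AF = NA_real_) {
  shape <- as.integer(shape)
  if (length(shape) < 1L || length(shape) > 3L || any(shape < 1L))
    stop("'shape' must give 1-3 side lengths >= 1")
  n <- prod(shape)
  bonds <- as.data.frame(bonds)
  stopifnot(all(c("i", "j", "J") %in% names(bonds)))
  bonds$i <- as.integer(bonds$i); bonds$j <- as.integer(bonds$j)
  if (nrow(bonds) > 0L) {
    if (any(bonds$i < 1L | bonds$i > n | bonds$j < 1L | bonds$j > n |
            bonds$i == bonds$j))
      stop("bond endpoints must be distinct valid site indices")
    if (any(abs(abs(bonds$J) - U) > 1e-12))
      stop("every coupling must have magnitude U")
  }
  if (!is.na(p_AF) && (p_AF < 0 || p_AF > 1))
    stop("'p_AF' must lie in [0, 1]")
  structure(list(shape = shape, n_sites = n, bonds = bonds,
                 h = as.numeric(h), U = as.numeric(U), p_AF = p_AF),
            class = "spin_system")
}

#' @export
print.spin_system <- function(x, ...) {
  cat(sprintf("Ising spin system: %s lattice, %d sites, %d bonds (%d AF, %d FM), h = %g\n",
              paste(x$shape, collapse = "x"), x$n_sites, nrow(x$bonds),
              sum(x$bonds$J < 0), sum(x$bonds$J > 0), x$h))
  invisible(x)
}

#' Random nearest-neighbor spin lattice
#'
#' Builds an open-boundary (non-periodic) grid of 1-3 dimensions and draws
#' each nearest-neighbor coupling independently: \code{-U} (antiferromagnetic)
#' with probability \code{p_AF}, else \code{+U} (ferromagnetic). The draw is a
#' pure function of \code{(shape, p_AF, U, h, seed)}.
#'
#' @inheritParams spin_system
#' @param p_AF probability that a bond is antiferromagnetic, in [0, 1].
#' @param seed integer seed for the coupling draw.
#' @return a \code{"spin_system"}.
#' @examples
#' chain <- make_spin_lattice(10, p_AF = 1, seed = 1)   # AF chain, 9 bonds
#' make_spin_lattice(c(4, 4), p_AF = 0, seed = 1)       # FM 4x4, 24 bonds
#' @export
make_spin_lattice <- function(shape, p_AF = 0.5, U = 1, h = 0, seed = 1L) {
  if (!is.numeric(p_AF) || length(p_AF) != 1L || p_AF < 0 || p_AF > 1)
    stop("'p_AF' must lie in [0, 1]")
  shape <- as.integer(shape)
  if (length(shape) < 1L || length(shape) > 3L || any(shape < 1L))
    stop("'shape' must give 1-3 side lengths >= 1")
  dims <- c(shape, rep(1L, 3L - length(shape)))
  n <- prod(dims)
  idx <- arrayInd(seq_len(n), dims)
  stride <- c(1L, dims[1], dims[1] * dims[2])
  bi <- integer(); bj <- integer()
  for (d in seq_along(dims)) {
    if (dims[d] < 2L) next
    from <- which(idx[, d] < dims[d])
    bi <- c(bi, from)
    bj <- c(bj, from + stride[d])
  }
  ord <- order(bi, bj)
  bi <- bi[ord]; bj <- bj[ord]
  J <- local_seed(seed, {
    ifelse(stats::runif(length(bi)) < p_AF, -U, +U)
  })
  spin_system(shape, data.frame(i = bi, j = bj, J = J), h = h, U = U,
              p_AF = p_AF)
}

#' Ring of spins with uniform coupling
#'
#' A 1-D chain of \code{n} spins closed into a ring (site n coupled back to
#' site 1), every bond \code{+U} (ferromagnetic) or \code{-U}
#' (antiferromagnetic). An AF ring of even length is satisfiable by
#' alternation; odd AF rings are frustrated.
#'
#' @param n number of spins (>= 3).
#' @param antiferromagnetic if TRUE all couplings are \code{-U}.
#' @inheritParams spin_system
#' @export
make_spin_ring <- function(n, antiferromagnetic = TRUE, U = 1, h = 0) {
  n <- as.integer(n)
  if (n < 3L) stop("a ring needs at least 3 spins")
  J <- rep(if (antiferromagnetic) -U else U, n)
  bonds <- data.frame(i = seq_len(n), j = c(seq_len(n - 1L) + 1L, 1L), J = J)
  spin_system(n, bonds, h = h, U = U,
              p_AF = if (antiferromagnetic) 1 else 0)
}

#' Ising energy of a spin configuration
#'
#' Evaluates \eqn{H = -\sum_{(i,j)} J_{ij} S_i S_j - h \sum_i S_i} exactly.
#'
#' @param system a \code{"spin_system"}.
#' @param config numeric vector of per-site spins, each \code{+1} or
#'   \code{-1}.
#' @return the energy (scalar).
#' @export
ising_energy <- function(system, config) {
  stopifnot(inherits(system, "spin_system"))
  s <- as.numeric(config)
  if (length(s) != system$n_sites)
    stop("configuration must assign every lattice site")
  if (!all(s %in% c(-1, 1)))
    stop("spins must be +1 or -1")
  b <- system$bonds
  -sum(b$J * s[b$i] * s[b$j]) - system$h * sum(s)
}

#' Map a spin system to a binary CSP
#'
#' Each site becomes a variable with domain \code{{+1, -1}}; each
#' ferromagnetic bond becomes a positive (values-equal) constraint and each
#' antiferromagnetic bond a negative (values-differ) constraint. Counting the
#' violated constraints of a configuration counts its frustrated bonds, so
#' lower Ising energy corresponds exactly to more satisfied constraints.
#'
#' @param system a \code{"spin_system"}.
#' @return a \code{"csp"} with the system kept in \code{$meta$spin_system}.
#' @export
csp_from_spin_system <- function(system) {
  stopifnot(inherits(system, "spin_system"))
  b <- system$bonds
  cons <- if (nrow(b)) data.frame(i = b$i, j = b$j, sign = sign(b$J)) else NULL
  csp(domains = rep(list(c("+1", "-1")), system$n_sites), constraints = cons,
      labels = paste0("s", seq_len(system$n_sites)),
      meta = list(problem = "spin_system", spin_system = system))
}

#' Decode a CSP assignment back to spins
#'
#' @param assignment domain indices from a spin-system CSP (1 = +1, 2 = -1).
#' @return numeric spins, \code{NA} where undecided.
#' @export
spins_from_assignment <- function(assignment) {
  c(1, -1)[as.integer(assignment)]
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's state.
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
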