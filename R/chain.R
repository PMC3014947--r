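# Lattice conformations: N x 3 integer matrices of monomer reference corners.
# Each monomer occupies the 2x2x2 cube of sites whose minimal corner is its
# coordinate row; excluded volume means no site is covered by two cubes, which
# for corner coordinates is a Chebyshev-distance > 1 condition.

#' Validate a lattice conformation
#'
#' Checks the three invariants of a bond-fluctuation-model conformation:
#' every consecutive bond vector belongs to the allowed 108-vector set, no
#' lattice site is covered by more than one monomer cube, and coordinates are
#' integer.
#'
#' @param positions N x 3 integer matrix of monomer reference corners.
#' @param loops Optional loop table (see [dl_loopset()]); when given, every
#'   active loop pair must also satisfy the co-localization constraint.
#' @param coloc_threshold Co-localization distance bound (lattice units).
#' @return `TRUE` invisibly, or an error describing the first violation.
#' @export
dl_validate_conformation <- function(positions, loops = NULL, coloc_threshold = 3) {
  positions <- as_positions(positions)
  n <- nrow(positions)
  if (n >= 2L) {
    d <- positions[-1L, , drop = FALSE] - positions[-n, , drop = FALSE]
    bad <- which(!dl_bond_allowed(d))
    if (length(bad))
      stop("bond ", bad[1L], " -> ", bad[1L] + 1L, " is not an allowed bond vector: (",
           paste(d[bad[1L], ], collapse = ","), ")")
    # cube overlap <=> max-norm of corner difference <= 1
    for (i in seq_len(n - 1L)) {
      rest <- positions[(i + 1L):n, , drop = FALSE]
      cheb <- pmax(abs(rest[, 1L] - positions[i, 1L]),
                   abs(rest[, 2L] - positions[i, 2L]),
                   abs(rest[, 3L] - positions[i, 3L]))
      if (any(cheb <= 1L))
        stop("excluded volume violated at monomer ", i)
    }
  }
  if (!is.null(loops) && nrow(loops)) {
    ok <- dl_loop_constraint_ok(positions, loops, coloc_threshold)
    if (!ok) stop("an active loop violates the co-localization constraint")
  }
  invisible(TRUE)
}

as_positions <- function(positions) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) stop("positions must have 3 columns")
  if (nrow(positions) < 1L) stop("N must be >= 1")
  if (any(positions != round(positions))) stop("coordinates must be integer")
  storage.mode(positions) <- "integer"
  positions
}

#' Initialize a chain conformation
#'
#' Builds a regular conformation with all bonds of the (2,0,0) class, folded
#' as a space-filling zig-zag into a near-cubic box so that even long chains
#' start compact (a fully stretched rod of more than ~120 monomers would
#' approach the period of the occupancy lattice used by the move kernel).
#' The snake trivially satisfies all invariants; optionally it is pre-relaxed
#' with self-avoiding-walk sweeps.  Production runs equilibrate much longer
#' via [dl_simulate()]; this constructor only guarantees validity and
#' seed-determinism.
#'
#' @param N Number of monomers (>= 1).
#' @param seed Optional integer seed; when given, `set.seed(seed)` is applied
#'   before the relaxation sweeps.
#' @param relax_sweeps Self-avoiding-walk sweeps applied to the stretched
#'   initial state (0 = return the stretched conformation).
#' @return N x 3 integer matrix of monomer reference corners.
#' @examples
#' conf <- dl_init_chain(16, seed = 1, relax_sweeps = 50)
#' dl_validate_conformation(conf)
#' @export
dl_init_chain <- function(N, seed = NULL, relax_sweeps = 0L) {
  N <- as.integer(N)
  if (is.na(N) || N < 1L) stop("N must be >= 1")
  # snake through an Lx x Ly x inf box on the even sublattice: +/-x runs,
  # (0,2,0) row turns, (0,0,2) plane turns -- all in the (2,0,0) bond class
  side <- max(1L, as.integer(ceiling(N^(1/3))))
  idx <- seq_len(N) - 1L
  ix <- idx %% side
  iy <- (idx %/% side) %% side
  iz <- idx %/% (side * side)
  # boustrophedon: the x direction alternates with the global row index
  # (iz * side + iy) so the path stays continuous across plane boundaries,
  # and the y direction alternates with the plane index
  row <- iz * side + iy
  ix <- ifelse(row %% 2L == 0L, ix, side - 1L - ix)
  iy <- ifelse(iz %% 2L == 0L, iy, side - 1L - iy)
  pos <- cbind(x = 2L * as.integer(ix), y = 2L * as.integer(iy),
               z = 2L * as.integer(iz))
  if (relax_sweeps > 0L) {
    if (!is.null(seed)) set.seed(seed)
    run <- cpp_run_bfm(pos, empty_loops(), as.integer(relax_sweeps),
                       0, 1, 3, 0L, as.integer(relax_sweeps))
    pos <- run$positions
    colnames(pos) <- c("x", "y", "z")
  }
  pos
}

empty_loops <- function() matrix(integer(0), 0L, 3L,
                                 dimnames = list(NULL, c("i", "j", "lifetime")))

#' Propose a single local Monte Carlo move
#'
#' Attempts to displace one monomer by one lattice unit.  The move is accepted
#' iff (a) all bonds incident to the moved monomer remain in the allowed set,
#' (b) the destination cube covers no site of another monomer, and (c) every
#' active loop involving the monomer still satisfies the co-localization
#' constraint.  Rejection is a normal outcome and leaves the conformation
#' unchanged.
#'
#' @param positions N x 3 integer matrix.
#' @param monomer Index in 1..N of the monomer to move.
#' @param direction One of the six unit lattice vectors.
#' @param loops Active loop table (default none).
#' @param coloc_threshold Loop enforcement distance (lattice units).
#' @return List with `accepted` (flag) and `positions` (updated or unchanged).
#' @export
dl_trial_move <- function(positions, monomer, direction, loops = empty_loops(),
                          coloc_threshold = 3) {
  positions <- as_positions(positions)
  direction <- as.integer(direction)
  if (length(direction) != 3L || sum(abs(direction)) != 1L)
    stop("direction must be one of the 6 unit lattice vectors")
  monomer <- as.integer(monomer)
  if (monomer < 1L || monomer > nrow(positions)) stop("monomer index out of range")
  res <- cpp_trial_move(positions, monomer, direction, loop_matrix(loops),
                        coloc_threshold)
  colnames(res$positions) <- c("x", "y", "z")
  res
}

#' Run raw Monte Carlo sweeps
#'
#' Low-level driver around the compiled kernel: one sweep is N trial moves,
#' each followed by one loop-formation event (one monomer picked at random;
#' if it has co-localized, not-yet-looped partners, one partner is picked
#' uniformly and a loop is formed with probability `p` and a Poisson(`lambda`)
#' lifetime).  Lifetimes are decremented once per sweep and expired loops are
#' removed.  Most users want [dl_simulate()], which adds equilibration,
#' autocorrelation measurement and thinning on top.
#'
#' @param positions Starting conformation (N x 3 integer matrix).
#' @param sweeps Number of Monte Carlo sweeps.
#' @param p Loop formation probability in `[0, 1]`.
#' @param lambda Mean of the Poisson lifetime distribution (sweeps).
#' @param loops Starting loop table (for resuming runs).
#' @param coloc_threshold Co-localization distance bound (lattice units,
#'   strict `<`).
#' @param store_every Store a conformation snapshot every this many sweeps
#'   (0 = none).
#' @param record_every Record the observable series (squared radius of
#'   gyration, loop count, acceptance fraction) every this many sweeps.
#' @return List with final `positions` and `loops`, snapshot list `stored`
#'   (+`stored_at` sweep indices), series `sweep`, `rg2`, `loop_count`,
#'   `acceptance`, and `span_max`, the largest single-axis extent seen.
#' @export
dl_run_sweeps <- function(positions, sweeps, p = 0, lambda = 1,
                          loops = empty_loops(), coloc_threshold = 3,
                          store_every = 0L, record_every = 1L) {
  positions <- as_positions(positions)
  stopifnot(sweeps >= 1, p >= 0, p <= 1, lambda > 0)
  out <- cpp_run_bfm(positions, loop_matrix(loops), as.integer(sweeps),
                     p, lambda, coloc_threshold,
                     as.integer(store_every), as.integer(record_every))
  if (out$span_max > 250)
    warning("chain span ", out$span_max,
            " approaches the occupancy lattice period (256); results unreliable")
  colnames(out$positions) <- c("x", "y", "z")
  out
}

loop_matrix <- function(loops) {
  if (is.null(loops) || nrow(loops) == 0L) return(empty_loops())
  m <- as.matrix(loops[, c(1L, 2L, 3L)])
  storage.mode(m) <- "integer"
  m
}
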