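# Loop dynamics: stochastic formation, enforcement and decay of intra-chain
# loops.  The compiled kernel performs these operations inside production
# runs; the functions here are the reference implementations of the same
# rules, used for unit-scale work and for cross-checking the kernel.

#' Construct a loop table
#'
#' A loop set is a data frame with columns `i`, `j` (monomer indices, `i < j`,
#' `j - i >= 2`) and `lifetime` (remaining lifetime in sweeps).  At most one
#' active loop may exist per unordered pair.
#'
#' @param i,j Monomer indices.
#' @param lifetime Remaining lifetimes (sweeps).
#' @export
dl_loopset <- function(i = integer(), j = integer(), lifetime = numeric()) {
  ii <- pmin(as.integer(i), as.integer(j))
  jj <- pmax(as.integer(i), as.integer(j))
  if (any(jj - ii < 2L)) stop("loops require |i - j| >= 2")
  if (anyDuplicated(paste(ii, jj))) stop("duplicate loop on a pair")
  if (any(lifetime < 0)) stop("lifetimes must be non-negative")
  data.frame(i = ii, j = jj, lifetime = as.numeric(lifetime))
}

#' Co-localized partners of a monomer
#'
#' Returns, in ascending order, all monomers `j` with `|i - j| >= 2` whose
#' Euclidean distance to monomer `i` is strictly less than `threshold`
#' lattice units.  Nearest neighbours along the chain are excluded: they are
#' trivially close and already bonded.
#'
#' @param positions N x 3 integer matrix.
#' @param i Query monomer (1-based).
#' @param threshold Co-localization bound (default 3 lattice units).
#' @export
dl_colocalized_partners <- function(positions, i, threshold = 3) {
  positions <- as_positions(positions)
  i <- as.integer(i)
  d2 <- (positions[, 1L] - positions[i, 1L])^2 +
        (positions[, 2L] - positions[i, 2L])^2 +
        (positions[, 3L] - positions[i, 3L])^2
  which(d2 < threshold^2 & abs(seq_len(nrow(positions)) - i) >= 2L)
}

#' Attempt one loop-formation event
#'
#' One monomer is chosen uniformly at random.  If its set of co-localized
#' partners not already looped to it is non-empty, one partner is chosen
#' uniformly and a loop is created with probability `p`; its lifetime is
#' drawn from a Poisson distribution with mean `lambda` (a lifetime of 0
#' dissolves at the end of the creation sweep).
#'
#' @param positions N x 3 integer matrix.
#' @param loops Current loop table.
#' @param p Loop formation probability.
#' @param lambda Poisson mean lifetime (sweeps).
#' @param coloc_threshold Co-localization bound (lattice units).
#' @return Possibly extended loop table.
#' @export
dl_attempt_loop_event <- function(positions, loops = dl_loopset(), p, lambda,
                                  coloc_threshold = 3) {
  positions <- as_positions(positions)
  m <- sample.int(nrow(positions), 1L)
  partners <- dl_colocalized_partners(positions, m, coloc_threshold)
  if (length(partners)) {
    looped <- c(loops$j[loops$i == m], loops$i[loops$j == m])
    partners <- setdiff(partners, looped)
  }
  if (!length(partners)) return(loops)
  jj <- if (length(partners) == 1L) partners else sample(partners, 1L)
  if (stats::runif(1L) < p) {
    life <- stats::rpois(1L, lambda)
    loops <- rbind(loops, dl_loopset(m, jj, life))
  }
  loops
}

#' Decay loop lifetimes
#'
#' Decrements every remaining lifetime by `elapsed` sweeps and removes loops
#' whose lifetime has reached zero or below.
#'
#' @param loops Loop table.
#' @param elapsed Elapsed sweeps (>= 0).
#' @export
dl_decay_loops <- function(loops, elapsed) {
  stopifnot(elapsed >= 0)
  if (elapsed == 0 || nrow(loops) == 0L) return(loops)
  loops$lifetime <- loops$lifetime - elapsed
  loops[loops$lifetime > 0, , drop = FALSE]
}

#' Check the loop enforcement constraint
#'
#' `TRUE` iff every active loop's monomer pair is strictly within the
#' co-localization threshold.  This is condition (c) of move acceptance: an
#' active loop constrains its pair to remain co-localized until it expires.
#'
#' @inheritParams dl_decay_loops
#' @param positions N x 3 integer matrix.
#' @param coloc_threshold Enforcement distance (lattice units, strict `<`).
#' @export
dl_loop_constraint_ok <- function(positions, loops, coloc_threshold = 3) {
  if (nrow(loops) == 0L) return(TRUE)
  positions <- as_positions(positions)
  d2 <- rowSums((positions[loops$i, , drop = FALSE] -
                 positions[loops$j, , drop = FALSE])^2)
  all(d2 < coloc_threshold^2)
}

#' Time-averaged number of simultaneous loops
#'
#' Average of a loop-count series from a post-equilibration run, with a
#' standard error that accounts for autocorrelation via the integrated
#' autocorrelation time of the series (`se = sd * sqrt(2 tau_int / T)`).
#'
#' @param counts Per-sweep (or per-record-point) active loop counts.
#' @return List with `mean`, `se` and `tau_int` (in record units).
#' @export
dl_mean_loop_count <- function(counts) {
  if (!length(counts)) stop("empty loop-count series")
  m <- mean(counts)
  if (stats::var(counts) == 0 || length(counts) < 100L)
    return(list(mean = m, se = 0, tau_int = NA_real_))
  tau <- dl_autocorrelation_time(counts)$tau_int
  list(mean = m, se = stats::sd(counts) * sqrt(2 * tau / length(counts)),
       tau_int = tau)
}
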