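# Size, shape, orientation and time-series observables.

#' Gyration tensor of a set of monomer positions
#'
#' `T_ab = (1/N) sum_i (x_ia - xbar_a)(x_ib - xbar_b)`; symmetric positive
#' semidefinite, trace equal to the squared radius of gyration.
#'
#' @param positions N x 3 matrix (any numeric coordinates; lattice corners and
#'   cube centers give identical central moments).
#' @return 3 x 3 symmetric matrix.
#' @export
dl_gyration_tensor <- function(positions) {
  positions <- as.matrix(positions)
  if (nrow(positions) < 1L) stop("empty position set")
  ctr <- sweep(positions, 2L, colMeans(positions))
  crossprod(ctr) / nrow(positions)
}

#' Normalized asphericity from gyration-tensor eigenvalues
#'
#' `A = [(l1-l2)^2 + (l2-l3)^2 + (l3-l1)^2] / [2 (l1+l2+l3)^2]`, a
#' dimensionless shape invariant in `[0, 1]`: 0 for a spherically symmetric
#' mass distribution (all eigenvalues equal) and 1 for a rod (one non-zero
#' eigenvalue).
#'
#' @param eigenvalues The three gyration-tensor eigenvalues (any order).
#' @export
dl_asphericity <- function(eigenvalues) {
  stopifnot(length(eigenvalues) == 3L, all(eigenvalues >= -1e-12))
  tr <- sum(eigenvalues)
  if (tr <= 0) stop("asphericity undefined for an all-zero gyration tensor")
  l <- eigenvalues
  ((l[1] - l[2])^2 + (l[2] - l[3])^2 + (l[3] - l[1])^2) / (2 * tr^2)
}

#' Full shape statistics of one conformation
#'
#' @param positions N x 3 matrix.
#' @return List with `rg2`, sorted `eigenvalues` (decreasing), the
#'   `principal_axis` unit vector of the largest eigenvalue, `asphericity`,
#'   and `degenerate` (TRUE when the two largest eigenvalues coincide to
#'   relative tolerance 1e-9, in which case the principal axis is chosen
#'   deterministically but the alignment angle is not meaningful).
#' @export
dl_shape_stats <- function(positions) {
  tensor <- dl_gyration_tensor(positions)
  e <- eigen(tensor, symmetric = TRUE)
  ev <- e$values
  axis <- e$vectors[, 1L]
  # deterministic headless representative: flip so the largest-magnitude
  # component (first on ties) is positive
  k <- which.max(abs(axis))
  if (axis[k] < 0) axis <- -axis
  list(rg2 = sum(ev), eigenvalues = ev, principal_axis = axis,
       asphericity = dl_asphericity(ev),
       degenerate = (ev[1] - ev[2]) < 1e-9 * max(sum(ev), 1))
}

#' Angle between two headless principal axes
#'
#' `acos(|a . b| / (|a| |b|))` in degrees, range `[0, 90]`; invariant under
#' sign flips of either axis.  For two independently, uniformly oriented axes
#' the mean is 1 radian = 57.2958 degrees, the reference value for chains
#' adjusted independently of each other.
#'
#' @param axis_a,axis_b Non-zero 3-vectors.
#' @export
dl_principal_axis_angle <- function(axis_a, axis_b) {
  na <- sqrt(sum(axis_a^2)); nb <- sqrt(sum(axis_b^2))
  if (na == 0 || nb == 0) stop("zero axis vector")
  acos(min(1, abs(sum(axis_a * axis_b)) / (na * nb))) * 180 / pi
}

#' Integrated autocorrelation time by self-consistent windowing
#'
#' Computes the normalized autocorrelation function of a scalar Monte Carlo
#' series (via FFT) and the integrated autocorrelation time
#' `tau_int = 1/2 + sum_{t=1}^{W} rho(t)`, with the window `W` chosen
#' self-consistently as the smallest lag satisfying `W >= c * tau_int(W)`
#' (c = 6 by default).  Under this convention white noise gives
#' `tau_int = 0.5` and an AR(1) process with coefficient `phi` gives
#' `(1 + phi) / (2 (1 - phi))`.
#'
#' @param x Scalar series (length >= 100, non-constant).
#' @param c_window Window constant `c`.
#' @param max_lag Longest lag of the autocorrelation function to compute
#'   (default `length(x) %/% 2`).
#' @return List with `tau_int`, `window`, and `acf` (values at lags
#'   `0..max_lag`).  Warns when the window exceeds a tenth of the series,
#'   i.e. when the series is too short for a reliable estimate.
#' @export
dl_autocorrelation_time <- function(x, c_window = 6, max_lag = NULL) {
  n <- length(x)
  if (n < 100L) stop("series too short for autocorrelation analysis (need >= 100)")
  if (stats::var(x) == 0) stop("constant series: autocorrelation time undefined")
  if (is.null(max_lag)) max_lag <- n %/% 2L
  max_lag <- min(max_lag, n - 1L)
  # FFT autocovariance with zero padding
  xc <- x - mean(x)
  m <- 2L^ceiling(log2(2L * n))
  f <- stats::fft(c(xc, rep(0, m - n)))
  ac <- Re(stats::fft(f * Conj(f), inverse = TRUE))[1:(max_lag + 1L)]
  ac <- ac / seq(n, n - max_lag)  # unbiased normalization per lag
  rho <- ac / ac[1L]
  tau <- 0.5
  W <- max_lag
  for (t in seq_len(max_lag)) {
    tau <- tau + rho[t + 1L]
    if (t >= c_window * tau) { W <- t; break }
  }
  if (W > n / 10)
    warning("autocorrelation window (", W, ") exceeds a tenth of the series; ",
            "tau_int estimate is unreliable")
  list(tau_int = max(tau, 0.5), window = W, acf = rho)
}

#' Thin a trajectory into decorrelated conformations
#'
#' Keeps stored conformations spaced at least `2 * tau_int` sweeps apart.
#'
#' @param stored List of conformations.
#' @param stored_at Sweep index of each stored conformation.
#' @param tau_int Integrated autocorrelation time in sweeps.
#' @return List with `conformations`, `kept_at` (their sweep indices) and
#'   `spacing` (the realized minimum spacing in sweeps).
#' @export
dl_thin_ensemble <- function(stored, stored_at, tau_int) {
  if (!length(stored)) stop("empty trajectory")
  spacing <- 2 * tau_int
  keep <- integer()
  last <- -Inf
  for (k in seq_along(stored_at)) {
    if (stored_at[k] - last >= spacing) { keep <- c(keep, k); last <- stored_at[k] }
  }
  if (!length(keep)) stop("trajectory shorter than the decorrelation spacing")
  list(conformations = stored[keep], kept_at = stored_at[keep],
       spacing = spacing)
}

# squared radius of gyration of one conformation
rg2_of <- function(positions) {
  ctr <- sweep(as.matrix(positions), 2L, colMeans(positions))
  sum(ctr^2) / nrow(positions)
}
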