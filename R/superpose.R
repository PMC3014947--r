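# Superposition estimator of the effective potential between two chain
# centers of mass, and accepted-pair structural statistics.
#
# Two independently equilibrated single-chain conformations are each rotated
# by a random element of the 48-element cubic symmetry group (lattice-exact),
# then the second is translated so the center-of-mass separation is as close
# as possible to the target r along the x axis.  The pair is accepted iff the
# occupied site sets are disjoint; U_eff(r) = -ln(N_acc / N_tot) in units of
# kT.  Shape statistics are computed over accepted trials only -- the
# conditional ensemble of the potential-of-mean-force framework.

#' One superposition trial
#'
#' @param conf_a,conf_b Valid conformations (N x 3 integer matrices).
#' @param target_r Target center-of-mass distance (lattice units, >= 0).
#' @return List with `accepted`, `realized_r`, `n_total = 1`.
#' @export
dl_superpose <- function(conf_a, conf_b, target_r) {
  stopifnot(target_r >= 0)
  res <- cpp_superpose(list(as_positions(conf_a)), list(as_positions(conf_b)),
                       target_r, 1L, 1L, FALSE)
  list(accepted = res$n_accepted == 1,
       realized_r = if (res$n_accepted == 1) res$mean_r_accepted else res$mean_r_all)
}

#' Site-set disjointness at an explicit shift
#'
#' Deterministic building block (no rotations, no center-of-mass targeting):
#' is the occupied site set of `conf_b + shift` disjoint from that of
#' `conf_a`?  Exposed for exact small-case validation of the acceptance rule,
#' e.g. against the hard-cube overlap result for single-monomer chains.
#'
#' @param conf_a,conf_b Conformations.
#' @param shifts Integer 3-vector or matrix of shifts (one per row).
#' @return Logical vector.
#' @export
dl_superpose_at_shift <- function(conf_a, conf_b, shifts) {
  if (is.null(dim(shifts))) shifts <- matrix(as.integer(shifts), nrow = 1L)
  storage.mode(shifts) <- "integer"
  cpp_sites_disjoint(as_positions(conf_a), as_positions(conf_b), shifts)
}

# shared driver: per r bin, run trials in batches until `target_accepted`
# acceptances or `max_trials`; returns aggregated statistics
superpose_bins <- function(ens_a, ens_b, r_grid, trials_per_bin,
                           target_accepted = 0, max_trials = NULL,
                           dens_half = 128L, collect_shapes = TRUE) {
  confs_a <- ensemble_confs(ens_a)
  confs_b <- ensemble_confs(ens_b)
  if (!length(confs_a) || !length(confs_b)) stop("empty ensemble")
  if (trials_per_bin < 1) stop("trials_per_bin must be positive")
  if (length(confs_a) < 100 || length(confs_b) < 100)
    warning("fewer than 100 conformations per ensemble; ",
            "superposition statistics may be under-resolved")
  if (is.null(max_trials)) max_trials <- trials_per_bin
  bins <- vector("list", length(r_grid))
  for (k in seq_along(r_grid)) {
    agg <- NULL
    repeat {
      res <- cpp_superpose(confs_a, confs_b, r_grid[k],
                           as.integer(trials_per_bin), as.integer(dens_half),
                           collect_shapes)
      agg <- if (is.null(agg)) res else merge_superpose(agg, res)
      if (agg$n_accepted >= target_accepted || agg$n_total >= max_trials) break
    }
    agg$target_r <- r_grid[k]
    bins[[k]] <- agg
  }
  bins
}

merge_superpose <- function(a, b) {
  out <- a
  for (f in c("n_total", "n_accepted", "sum_rg2", "n_chains", "sum_asph",
              "sum_asph2", "n_asph", "sum_angle", "sum_angle2", "n_angle",
              "n_degenerate"))
    out[[f]] <- a[[f]] + b[[f]]
  out$dens_a <- a$dens_a + b$dens_a
  out$dens_b <- a$dens_b + b$dens_b
  wa <- a$n_accepted; wb <- b$n_accepted
  out$mean_r_accepted <- if (wa + wb > 0) {
    sum(c(a$mean_r_accepted * wa, b$mean_r_accepted * wb), na.rm = TRUE) / (wa + wb)
  } else NA_real_
  out$mean_r_all <- (a$mean_r_all * a$n_total + b$mean_r_all * b$n_total) /
    (a$n_total + b$n_total)
  out
}

ensemble_confs <- function(x) {
  if (inherits(x, "dl_ensemble")) x$conformations
  else if (is.list(x) && !is.null(x$conformations)) x$conformations
  else if (is.list(x)) x
  else list(x)
}

#' Estimate the effective potential between two chain centers of mass
#'
#' For each target distance the acceptance fraction `f = n_acc / n_tot` of
#' superposition trials gives `U_eff = -ln f` (kT), with standard error
#' `sqrt((1 - f) / (f n_tot))` by binomial error propagation.  Bins with zero
#' acceptances are censored: `U_eff >= ln(n_tot)` is reported as a lower
#' bound (`censored = TRUE`) rather than an infinity.
#'
#' @param ensemble_a,ensemble_b `dl_ensemble` objects (or lists of
#'   conformations) of decorrelated single-chain snapshots.
#' @param r_grid Target center-of-mass distances (lattice units).
#' @param trials_per_bin Trials per batch and bin (>= 100).
#' @param target_accepted If positive, batches of `trials_per_bin` trials are
#'   repeated until this many acceptances (or `max_trials`) per bin --
#'   useful deep in the repulsive core.
#' @param max_trials Cap on total trials per bin.
#' @return A `dl_potential` data frame with columns `r` (mean realized
#'   center-of-mass distance of the bin), `r_over_rg`, `n_total`,
#'   `n_accepted`, `u_eff`, `stderr`, `censored`.  The isolated-chain
#'   `rg_iso` used for scaling is `attr(x, "rg_iso")` (from `ensemble_a`
#'   when available, else 1).
#' @examples
#' \donttest{
#' a <- dl_simulate(24, sweeps = 6000, seed = 1)
#' u <- dl_estimate_potential(a, a, r_grid = c(0, 4, 8, 16), trials_per_bin = 500)
#' u
#' }
#' @export
dl_estimate_potential <- function(ensemble_a, ensemble_b, r_grid,
                                  trials_per_bin = 1000L, target_accepted = 0,
                                  max_trials = NULL) {
  if (trials_per_bin < 100) stop("trials_per_bin must be >= 100")
  bins <- superpose_bins(ensemble_a, ensemble_b, r_grid, trials_per_bin,
                         target_accepted, max_trials, collect_shapes = FALSE)
  rg <- if (inherits(ensemble_a, "dl_ensemble")) ensemble_a$rg_iso else 1
  rows <- lapply(bins, function(b) {
    f <- b$n_accepted / b$n_total
    r <- if (b$n_accepted > 0) b$mean_r_accepted else b$mean_r_all
    data.frame(r = r, r_over_rg = r / rg, n_total = b$n_total,
               n_accepted = b$n_accepted,
               u_eff = if (f > 0) -log(f) else log(b$n_total),
               stderr = if (f > 0) sqrt((1 - f) / (f * b$n_total)) else NA_real_,
               censored = f == 0)
  })
  out <- do.call(rbind, rows)
  attr(out, "rg_iso") <- rg
  class(out) <- c("dl_potential", class(out))
  out
}

#' Ratio of two effective-potential curves
#'
#' Interpolates both curves linearly on the scaled distance `r / R_g` and
#' returns the per-bin ratio `q = u_loops / u_linear` with propagated
#' standard errors.  Bins where the denominator is consistent with zero
#' (within 2 standard errors) or censored are dropped with a message.
#'
#' @param curve_loops,curve_linear `dl_potential` objects.
#' @return Data frame with `r_over_rg`, `q`, `stderr`, and the interpolated
#'   `u_loops`, `u_linear`.
#' @export
dl_potential_ratio <- function(curve_loops, curve_linear) {
  grid <- curve_loops$r_over_rg
  lin_u <- stats::approx(curve_linear$r_over_rg, curve_linear$u_eff,
                         xout = grid, rule = 1)$y
  lin_se <- stats::approx(curve_linear$r_over_rg, curve_linear$stderr,
                          xout = grid, rule = 1)$y
  ok <- !is.na(lin_u) & !curve_loops$censored &
    !is.na(lin_se) & lin_u > 2 * lin_se
  if (any(!ok)) message("dropping ", sum(!ok),
                        " bin(s) where the linear potential is censored, ",
                        "outside range, or consistent with 0")
  q <- curve_loops$u_eff[ok] / lin_u[ok]
  se <- q * sqrt((curve_loops$stderr[ok] / curve_loops$u_eff[ok])^2 +
                 (lin_se[ok] / lin_u[ok])^2)
  data.frame(r_over_rg = grid[ok], q = q, stderr = se,
             u_loops = curve_loops$u_eff[ok], u_linear = lin_u[ok])
}

#' Accepted-pair shape and intermingling statistics
#'
#' From the accepted superposition trials at each target distance, computes
#' the conditional-ensemble structure of the pair: the swelling factor
#' `alpha(r)` (root-mean-square radius of gyration over accepted-pair chains
#' divided by the isolated-chain value), the asphericity ratio `A(r)/A_iso`,
#' the mean mutual alignment angle `beta(r)` between the chains' largest
#' gyration-tensor principal axes (57.296 deg for independent random
#' orientations), the monomer densities of both chains projected on the
#' center-of-mass axis (bins of 1 lattice unit, each normalized to unit
#' mass), and their overlap fraction `sum_k min(a_k, b_k)`.
#'
#' @inheritParams dl_estimate_potential
#' @param min_accepted Bins with fewer accepted trials are flagged
#'   `low_confidence`.
#' @return A `dl_shape_profile` data frame (one row per bin) with attributes
#'   `densities` (list of per-bin projected density tables) and the isolated
#'   references `rg_iso`, `asph_iso`.
#' @export
dl_pair_shape_profile <- function(ensemble_a, ensemble_b, r_grid,
                                  trials_per_bin = 1000L, target_accepted = 0,
                                  max_trials = NULL, min_accepted = 30L) {
  bins <- superpose_bins(ensemble_a, ensemble_b, r_grid, trials_per_bin,
                         target_accepted, max_trials, collect_shapes = TRUE)
  stats_a <- isolated_refs(ensemble_a)
  stats_b <- isolated_refs(ensemble_b)
  rg2_iso <- (stats_a$rg2 + stats_b$rg2) / 2
  asph_iso <- (stats_a$asph + stats_b$asph) / 2
  dens <- list()
  rows <- lapply(seq_along(bins), function(k) {
    b <- bins[[k]]
    na <- b$n_accepted
    grid <- seq_along(b$dens_a) - (length(b$dens_a) + 1L) / 2
    da <- if (sum(b$dens_a) > 0) b$dens_a / sum(b$dens_a) else b$dens_a
    db <- if (sum(b$dens_b) > 0) b$dens_b / sum(b$dens_b) else b$dens_b
    dens[[k]] <<- data.frame(s = grid, density_a = da, density_b = db)
    mean_asph <- if (b$n_asph > 0) b$sum_asph / b$n_asph else NA_real_
    sd_asph <- if (b$n_asph > 1)
      sqrt(pmax(0, b$sum_asph2 / b$n_asph - mean_asph^2)) else NA_real_
    mean_ang <- if (b$n_angle > 0) b$sum_angle / b$n_angle else NA_real_
    sd_ang <- if (b$n_angle > 1)
      sqrt(pmax(0, b$sum_angle2 / b$n_angle - mean_ang^2)) else NA_real_
    data.frame(
      r = if (na > 0) b$mean_r_accepted else b$mean_r_all,
      r_over_rg = (if (na > 0) b$mean_r_accepted else b$mean_r_all) /
        sqrt(rg2_iso),
      n_total = b$n_total, n_accepted = na,
      alpha = if (na > 0) sqrt((b$sum_rg2 / b$n_chains) / rg2_iso) else NA_real_,
      asph_ratio = mean_asph / asph_iso,
      asph_ratio_se = sd_asph / asph_iso / sqrt(pmax(1, b$n_asph)),
      beta_deg = mean_ang,
      beta_se = sd_ang / sqrt(pmax(1, b$n_angle)),
      n_degenerate = b$n_degenerate,
      overlap = if (na > 0) sum(pmin(da, db)) else NA_real_,
      low_confidence = na < min_accepted)
  })
  out <- do.call(rbind, rows)
  attr(out, "densities") <- dens
  attr(out, "rg_iso") <- sqrt(rg2_iso)
  attr(out, "asph_iso") <- asph_iso
  class(out) <- c("dl_shape_profile", class(out))
  out
}

isolated_refs <- function(x) {
  confs <- ensemble_confs(x)
  if (inherits(x, "dl_ensemble"))
    list(rg2 = x$rg2_iso, asph = x$asph_iso)
  else
    list(rg2 = mean(vapply(confs, rg2_of, numeric(1))),
         asph = mean(vapply(confs, function(m) dl_shape_stats(m)$asphericity,
                            numeric(1))))
}

#' Overlap fraction of two normalized projected densities
#'
#' `sum_k min(a_k, b_k)` over a common grid; 1 for identical distributions,
#' 0 for disjoint supports.
#'
#' @param density_a,density_b Non-negative vectors on the same grid, each
#'   summing to 1 (tolerance 1e-6).
#' @export
dl_overlap_fraction <- function(density_a, density_b) {
  if (length(density_a) != length(density_b)) stop("mismatched density grids")
  for (d in list(density_a, density_b))
    if (abs(sum(d) - 1) > 1e-6) stop("densities must be normalized to unit mass")
  sum(pmin(density_a, density_b))
}

#' @export
print.dl_potential <- function(x, ...) {
  cat("Effective potential curve (", nrow(x), " bins, rg_iso = ",
      format(attr(x, "rg_iso"), digits = 4), ")\n", sep = "")
  print.data.frame(x, digits = 4, row.names = FALSE)
  if (any(x$censored))
    cat("censored bins report the lower bound u_eff >= ln(n_total)\n")
  invisible(x)
}

#' @export
print.dl_shape_profile <- function(x, ...) {
  cat("Accepted-pair shape profile (", nrow(x), " bins)\n", sep = "")
  print.data.frame(x[, setdiff(names(x), "n_degenerate")], digits = 4,
                   row.names = FALSE)
  invisible(x)
}

#' @export
plot.dl_potential <- function(x, ..., xlab = "r / R_g",
                              ylab = expression(U[eff] / k[B] * T)) {
  open <- !x$censored
  plot(x$r_over_rg, x$u_eff, pch = ifelse(open, 19, 2), xlab = xlab,
       ylab = ylab, ...)
  ok <- open & !is.na(x$stderr)
  if (any(ok))
    suppressWarnings(graphics::arrows(
      x$r_over_rg[ok], x$u_eff[ok] - x$stderr[ok],
      x$r_over_rg[ok], x$u_eff[ok] + x$stderr[ok],
      angle = 90, code = 3, length = 0.02))
  invisible(x)
}
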