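# High-level simulation pipeline: equilibration, production, decorrelation
# diagnostics and thinning into an ensemble of independent conformations.

#' Derive a reproducible child seed from a master seed
#'
#' Every stochastic stage (chain relaxation, dynamics, superposition,
#' fixture synthesis) uses its own sub-stream seed derived deterministically
#' from the master seed and a purpose label, so whole workflows are
#' replayable from a single integer.
#'
#' @param master Master seed (integer).
#' @param purpose Character label of the sub-stream.
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
dl_derive_seed <- function(master, purpose) {
  h <- sum(utf8ToInt(purpose) * seq_along(utf8ToInt(purpose)))
  as.integer((as.numeric(master) * 48271 + h * 100003 + 1) %% 2147483646 + 1)
}

#' Simulate an isolated Dynamic Loop chromosome
#'
#' Runs the full single-chain pipeline:
#' \enumerate{
#'   \item build a stretched chain and equilibrate it as a self-avoiding walk
#'     (no loops) for `saw_sweeps` sweeps, measuring the integrated
#'     autocorrelation time `tau_saw` of the squared radius of gyration over
#'     the second half of the stage;
#'   \item if `p > 0`, switch loop formation on with Poisson mean lifetime
#'     `lambda = lifetime_multiplier * tau_saw` (or an explicit
#'     `lifetime_mean`) and run production sweeps;
#'   \item measure `tau_int` on the production series, discard the first
#'     `10 * tau_int` sweeps as burn-in, and thin the stored snapshots to at
#'     least `2 * tau_int` sweeps apart.
#' }
#' When `sweeps = NULL` the production stage is extended adaptively (in
#' chunks, re-measuring `tau_int`) until `n_conformations` decorrelated
#' snapshots have been collected or `max_sweeps` is reached.  A warning is
#' emitted when the production series is shorter than `50 * tau_int`.
#'
#' @param N Chain length (monomers).
#' @param p Loop formation probability in `[0, 1]` (0 = self-avoiding walk).
#' @param lifetime_multiplier Loop mean lifetime as a multiple of the
#'   SAW-calibrated `tau_int` at the same `N`.
#' @param lifetime_mean Explicit Poisson mean lifetime in sweeps (overrides
#'   `lifetime_multiplier`; also skips the need for a long calibration stage
#'   when supplied together with a short `saw_sweeps`).
#' @param sweeps Production sweeps, or `NULL` for adaptive extension.
#' @param n_conformations Target ensemble size under adaptive extension.
#' @param max_sweeps Hard cap on production sweeps.
#' @param saw_sweeps SAW equilibration/calibration sweeps (`NULL`: chosen
#'   adaptively so the stage covers at least ~60 tau of the SAW series).
#' @param store_every Snapshot interval in sweeps (`NULL`: chosen from an
#'   initial `tau_int` guess).
#' @param record_every Observable recording interval in sweeps.
#' @param coloc_threshold Co-localization distance bound (lattice units).
#' @param init Optional starting conformation (e.g. a decorrelated snapshot
#'   from an earlier SAW run at the same `N`).  When given together with an
#'   explicit `lifetime_mean` (or `p = 0`), the SAW calibration stage is
#'   skipped unless `saw_sweeps` asks for it.
#' @param loop_burn_sweeps Looping-phase equilibration: sweeps run with loop
#'   dynamics active but not recorded, between the SAW stage and production.
#'   The simultaneous loop count creeps up on the (slow) conformational
#'   timescale after loops are switched on; a pre-burn of ~30 conformational
#'   decorrelation times makes the recorded production series stationary.
#' @param thin_spacing Snapshot spacing for the returned ensemble, in sweeps.
#'   The default (`NULL`) is the conventional `2 * tau_int`, which makes the
#'   snapshots statistically independent by the R_g^2 criterion.  In the
#'   slowly-relaxing looping phase a denser spacing (e.g. one loop lifetime)
#'   retains many more snapshots whose loop sets have turned over -- useful
#'   for conditional (accepted-pair) statistics that must cover the tails of
#'   the shape distribution; `n_independent` in the result always reports
#'   the run length in units of `2 * tau_int`.
#' @param seed Master seed for the run.
#' @return A `dl_ensemble`: list with `conformations` (decorrelated N x 3
#'   snapshots), the observable series (`sweep`, `rg2`, `loop_count`,
#'   `acceptance`), diagnostics (`tau_int`, `tau_saw`, `spacing`,
#'   `mean_loop_count`, `rg_iso`, `asph_iso`) and the full parameter record
#'   in `params`.
#' @examples
#' ens <- dl_simulate(16, p = 0, sweeps = 2000, saw_sweeps = 500, seed = 1)
#' summary(ens)
#' @export
dl_simulate <- function(N, p = 0, lifetime_multiplier = 1, lifetime_mean = NULL,
                        sweeps = NULL, n_conformations = 200L,
                        max_sweeps = 2e7, saw_sweeps = NULL,
                        store_every = NULL, record_every = 1L,
                        coloc_threshold = 3, init = NULL,
                        loop_burn_sweeps = 0L, thin_spacing = NULL, seed = 1L) {
  stopifnot(N >= 1, p >= 0, p <= 1)
  t0 <- proc.time()[3]
  set.seed(dl_derive_seed(seed, "chain-init"))
  if (is.null(init)) {
    pos <- dl_init_chain(N)
  } else {
    pos <- as_positions(init)
    if (nrow(pos) != N) stop("init conformation has wrong chain length")
  }

  # --- stage 1: SAW equilibration / tau calibration ---
  # skipped when an equilibrated start and an explicit lifetime are supplied
  skip_saw <- !is.null(init) && (p == 0 || !is.null(lifetime_mean)) &&
    is.null(saw_sweeps)
  saw_adaptive <- is.null(saw_sweeps)
  if (is.null(saw_sweeps)) saw_sweeps <- max(2000L, 30L * N)
  set.seed(dl_derive_seed(seed, "saw-stage"))
  tau_saw <- if (!is.null(lifetime_mean)) lifetime_mean / max(lifetime_multiplier, 1e-12)
             else NA_real_
  saw <- list(rg2 = numeric(), sweep = integer(), span_max = 0L)
  grow <- as.integer(saw_sweeps)
  total_saw <- 0L
  if (!skip_saw) repeat {
    run <- cpp_run_bfm(pos, empty_loops(), grow, 0, 1, coloc_threshold,
                       0L, as.integer(record_every))
    pos <- run$positions
    saw <- if (is.null(saw)) run else
      list(rg2 = c(saw$rg2, run$rg2), sweep = c(saw$sweep, total_saw + run$sweep),
           span_max = max(saw$span_max, run$span_max))
    total_saw <- total_saw + grow
    half <- saw$rg2[(length(saw$rg2) %/% 2 + 1L):length(saw$rg2)]
    tau_saw <- suppressWarnings(dl_autocorrelation_time(half)$tau_int) * record_every
    # an adaptive stage must cover enough decorrelation times to trust tau_saw
    if (!saw_adaptive || total_saw >= 60 * tau_saw || total_saw >= max_sweeps) break
    grow <- as.integer(min(max(total_saw, ceiling(60 * tau_saw) - total_saw),
                           max_sweeps - total_saw))
    if (grow < 1L) break
  }

  if (p > 0) {
    lambda <- if (!is.null(lifetime_mean)) lifetime_mean
              else lifetime_multiplier * tau_saw
    if (is.na(lambda) || lambda <= 0) stop("loop lifetime mean must be positive")
  } else lambda <- 1

  # --- stage 2: production ---
  # timescale guess for snapshot spacing and chunk sizing: loop turnover
  # (lambda) bounds the conformational decorrelation time from below in the
  # looping phase; the measured tau_int takes over once the series exists
  tau_guess <- max(if (is.finite(tau_saw)) tau_saw else 1,
                   if (p > 0) lambda else 1)
  if (is.null(store_every))
    store_every <- max(1L, as.integer(ceiling(tau_guess / 4)))
  set.seed(dl_derive_seed(seed, "loop-burn"))
  loops <- empty_loops()
  if (p > 0 && loop_burn_sweeps > 0) {
    pre <- cpp_run_bfm(pos, loops, as.integer(loop_burn_sweeps), p, lambda,
                       coloc_threshold, 0L, as.integer(loop_burn_sweeps))
    pos <- pre$positions
    loops <- pre$loops
  }
  set.seed(dl_derive_seed(seed, "production"))
  adaptive <- is.null(sweeps)
  chunk <- if (adaptive) {
    as.integer(min(max_sweeps, ceiling((10 + 2.5 * n_conformations) * tau_guess)))
  } else as.integer(sweeps)
  series <- list(sweep = numeric(), rg2 = numeric(), loop_count = integer(),
                 acceptance = numeric())
  stored <- list(); stored_at <- numeric()
  total <- 0
  span_max <- saw$span_max
  repeat {
    run <- cpp_run_bfm(pos, loops, chunk, p, lambda, coloc_threshold,
                       as.integer(store_every), as.integer(record_every))
    pos <- run$positions
    loops <- run$loops
    series$sweep <- c(series$sweep, total + run$sweep)
    series$rg2 <- c(series$rg2, run$rg2)
    series$loop_count <- c(series$loop_count, run$loop_count)
    series$acceptance <- c(series$acceptance, run$acceptance)
    stored <- c(stored, run$stored)
    stored_at <- c(stored_at, total + run$stored_at)
    total <- total + chunk
    span_max <- max(span_max, run$span_max)
    nrec <- length(series$rg2)
    tau <- suppressWarnings(
      dl_autocorrelation_time(series$rg2[max(1L, nrec %/% 4L):nrec])$tau_int) *
      record_every
    burn <- min(10 * tau, total / 2)
    n_indep <- max(0, floor((total - burn) / (2 * tau)))
    if (!adaptive || n_indep >= n_conformations || total >= max_sweeps) break
    need <- ceiling(burn + 2 * tau * (n_conformations + 2) - total)
    chunk <- as.integer(min(max(need, 1000), max_sweeps - total))
    if (chunk < 1L) break
  }
  if (span_max > 250)
    warning("chain span ", span_max, " approaches the occupancy lattice period")

  # post-hoc decorrelation time, measured away from the initial transient
  # (the first quarter of the series), burn-in 10 tau capped at half the run
  nrec <- length(series$rg2)
  tail_idx <- max(1L, nrec %/% 4L):nrec
  tau <- suppressWarnings(dl_autocorrelation_time(series$rg2[tail_idx])$tau_int) *
    record_every
  burn <- min(10 * tau, total / 2)
  if (total < 50 * tau)
    warning("production run (", total, " sweeps) is shorter than 50 tau_int (",
            round(50 * tau), "); ensemble statistics may be unreliable")
  keep0 <- stored_at > burn
  if (!any(keep0)) keep0 <- stored_at > total / 2  # short fixed-length runs
  thin <- dl_thin_ensemble(stored[keep0], stored_at[keep0],
                           if (is.null(thin_spacing)) tau else thin_spacing / 2)
  post <- series$sweep > burn

  confs <- thin$conformations
  rg2s <- vapply(confs, rg2_of, numeric(1))
  asphs <- vapply(confs, function(m) dl_shape_stats(m)$asphericity, numeric(1))
  mlc <- if (p > 0) dl_mean_loop_count(series$loop_count[post])
         else list(mean = 0, se = 0, tau_int = NA_real_)

  structure(list(
    conformations = confs,
    kept_at = thin$kept_at,
    series = series,
    params = list(N = N, p = p, lifetime_multiplier = lifetime_multiplier,
                  lifetime_mean = lambda, coloc_threshold = coloc_threshold,
                  seed = seed, saw_sweeps = total_saw, production_sweeps = total,
                  store_every = store_every, record_every = record_every),
    tau_saw = tau_saw, tau_int = tau, spacing = thin$spacing, burn_in = burn,
    n_independent = floor((total - burn) / (2 * tau)),
    mean_loop_count = mlc$mean, se_loop_count = mlc$se,
    rg_iso = sqrt(mean(rg2s)), rg2_iso = mean(rg2s),
    asph_iso = mean(asphs), asph_iso_se = stats::sd(asphs) / sqrt(length(asphs)),
    mean_bond_length = mean_bond_length(confs),
    elapsed_s = unname(proc.time()[3] - t0)),
    class = "dl_ensemble")
}

mean_bond_length <- function(confs) {
  if (nrow(confs[[1]]) < 2L) return(NA_real_)
  mean(vapply(confs, function(m) {
    n <- nrow(m)
    mean(sqrt(rowSums((m[-1L, , drop = FALSE] - m[-n, , drop = FALSE])^2)))
  }, numeric(1)))
}

#' @export
print.dl_ensemble <- function(x, ...) {
  p <- x$params
  cat("Dynamic Loop ensemble: N =", p$N, " p =", p$p, "\n")
  cat(" ", length(x$conformations), "decorrelated conformations (spacing",
      format(x$spacing, digits = 3), "sweeps)\n")
  cat("  tau_int =", format(x$tau_int, digits = 4), "sweeps;",
      p$production_sweeps, "production sweeps\n")
  cat("  <R_g> =", format(x$rg_iso, digits = 4), "lattice units;",
      "<A> =", format(x$asph_iso, digits = 3), "\n")
  if (p$p > 0)
    cat("  mean simultaneous loops =", format(x$mean_loop_count, digits = 4),
        "(", format(x$mean_loop_count / p$N, digits = 3), "per monomer; lambda =",
        format(p$lifetime_mean, digits = 4), "sweeps )\n")
  invisible(x)
}

#' @export
summary.dl_ensemble <- function(object, ...) {
  print(object)
  cat("  mean bond length =", format(object$mean_bond_length, digits = 4),
      "lattice units\n")
  cat("  SAW stage:", object$params$saw_sweeps, "sweeps, tau_saw =",
      format(object$tau_saw, digits = 4), "\n")
  invisible(object)
}

#' Calibrate the looping probability to a target loop count
#'
#' Finds `p` such that the mean number of simultaneous loops per monomer
#' matches a target, by bisection on `log10(p)` with short probe runs.  The
#' mean loop count is monotone non-decreasing in `p`, which makes bisection
#' reliable; probe runs (equilibration plus measurement of a few loop
#' lifetimes each) trade precision for speed, so the returned `p` should be
#' followed by a full [dl_simulate()] run if a tight match is required.
#'
#' @param N Chain length.
#' @param target_loops_per_monomer Desired mean simultaneous loops per
#'   monomer.
#' @param lifetime_mean Poisson mean loop lifetime in sweeps (as in
#'   [dl_simulate()]).
#' @param probe_sweeps Sweeps per probe run (`NULL`: `6 * lifetime_mean`,
#'   min 2000).
#' @param tol Relative tolerance on the loop count.
#' @param max_iter Bisection iterations.
#' @param coloc_threshold Co-localization distance bound (lattice units).
#' @param init Optional equilibrated SAW conformation to start each probe
#'   from (recommended: a snapshot from a [dl_simulate()] run at the same N;
#'   the default stretched-snake start biases probes towards compact,
#'   loop-rich states).
#' @param seed Master seed.
#' @return List with `p`, `achieved` loops per monomer, and the probe `trace`.
#' @export
dl_calibrate_p <- function(N, target_loops_per_monomer, lifetime_mean,
                           probe_sweeps = NULL, tol = 0.08, max_iter = 14L,
                           coloc_threshold = 3, init = NULL,
                        loop_burn_sweeps = 0L, thin_spacing = NULL, seed = 1L) {
  stopifnot(target_loops_per_monomer > 0, lifetime_mean > 0)
  if (is.null(probe_sweeps))
    probe_sweeps <- max(2000L, as.integer(6 * lifetime_mean))
  start <- if (is.null(init)) dl_init_chain(N, seed = seed, relax_sweeps = 20L * N)
           else as_positions(init)
  probe <- function(p, k) {
    set.seed(dl_derive_seed(seed, paste0("calib-", k)))
    run <- cpp_run_bfm(start, empty_loops(), as.integer(probe_sweeps), p,
                       lifetime_mean, coloc_threshold, 0L, 4L)
    burn <- length(run$loop_count) %/% 2
    mean(run$loop_count[(burn + 1L):length(run$loop_count)]) / N
  }
  lo <- 1e-8; hi <- 1
  y_hi <- probe(hi, 0)
  if (y_hi < target_loops_per_monomer * (1 - tol)) {
    warning("target loop density ", target_loops_per_monomer,
            " unreachable even at p = 1 (got ", round(y_hi, 3), ")")
    return(list(p = 1, achieved = y_hi,
                trace = data.frame(p = 1, loops_per_monomer = y_hi)))
  }
  trace <- data.frame(p = hi, loops_per_monomer = y_hi)
  best <- list(p = hi, achieved = y_hi)
  for (it in seq_len(max_iter)) {
    mid <- sqrt(lo * hi)
    y <- probe(mid, it)
    trace <- rbind(trace, data.frame(p = mid, loops_per_monomer = y))
    if (abs(y - target_loops_per_monomer) <
        abs(best$achieved - target_loops_per_monomer))
      best <- list(p = mid, achieved = y)
    if (abs(y / target_loops_per_monomer - 1) < tol) break
    if (y < target_loops_per_monomer) lo <- mid else hi <- mid
  }
  c(best, list(trace = trace))
}
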