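# Mapping lattice/bead units to physical nm/kb units by matching
# mean-square-distance curves to FISH-style data, plus a synthetic
# fixture generator for such tables.

#' Model mean-square-distance curve
#'
#' For each genomic lag `g = s * kb_per_bead`, the ensemble and segment
#' average of the squared spatial distance between monomers `s` apart along
#' the chain (all `(i, i + s)` pairs, chain ends included, assuming
#' translation invariance along the chain).
#'
#' @param ensemble `dl_ensemble` or list of conformations.
#' @param kb_per_bead Genomic content of one monomer (kb).
#' @param lags Chain lags `s` to evaluate (default all `1..N-1`).
#' @param trim_ends Drop pairs whose members lie within this many monomers of
#'   either chain end.  Chain ends are floppier than interior segments, so
#'   untrimmed curves bend upward at large lags even when the interior has
#'   reached its territory plateau; `trim_ends = N %/% 4` gives a cleaner
#'   leveling-off diagnostic.
#' @return A `dl_msd_curve` data frame: `genomic_kb`, `msd` (lattice units
#'   squared), `source = "model"`.
#' @export
dl_model_msd_curve <- function(ensemble, kb_per_bead = 400, lags = NULL,
                               trim_ends = 0L) {
  confs <- ensemble_confs(ensemble)
  if (!length(confs)) stop("empty ensemble")
  N <- nrow(confs[[1]])
  lo <- 1L + as.integer(trim_ends); hi <- N - as.integer(trim_ends)
  if (is.null(lags)) lags <- seq_len(hi - lo)
  stopifnot(all(lags >= 1), all(lags <= hi - lo))
  msd <- vapply(lags, function(s) {
    mean(vapply(confs, function(m) {
      i <- lo:(hi - s)
      mean(rowSums((m[i + s, , drop = FALSE] - m[i, , drop = FALSE])^2))
    }, numeric(1)))
  }, numeric(1))
  out <- data.frame(genomic_kb = lags * kb_per_bead, msd = msd,
                    source = "model", stringsAsFactors = FALSE)
  class(out) <- c("dl_msd_curve", class(out))
  out
}

#' Synthesize a FISH-style mean-square-distance table
#'
#' Emits a saturating curve `m(g) = plateau * (1 - exp(-g / crossover))` with
#' multiplicative lognormal noise, mimicking interphase FISH measurements of
#' mean square spatial distance (um^2) against genomic separation (kb).
#' Deterministic given the seed.
#'
#' @param genomic_kb Genomic separations (kb, strictly increasing).
#' @param plateau Large-separation plateau (um^2).
#' @param crossover Genomic crossover scale (kb).
#' @param noise Lognormal sdlog of the multiplicative noise (0 = none).
#' @param seed Integer seed.
#' @return A `dl_msd_curve` data frame with `source = "synthetic-fish"`.
#' @export
dl_synthesize_fish_curve <- function(genomic_kb = seq(400, 40000, by = 400),
                                     plateau = 9, crossover = 5000,
                                     noise = 0.05, seed = 1L) {
  if (plateau <= 0 || crossover <= 0 || noise < 0) stop("non-positive parameters")
  if (any(diff(genomic_kb) <= 0)) stop("genomic separations must be increasing")
  set.seed(seed)
  m <- plateau * (1 - exp(-genomic_kb / crossover))
  if (noise > 0) m <- m * stats::rlnorm(length(m), meanlog = 0, sdlog = noise)
  out <- data.frame(genomic_kb = genomic_kb, msd = m,
                    source = "synthetic-fish", stringsAsFactors = FALSE)
  class(out) <- c("dl_msd_curve", class(out))
  out
}

#' Fit the lattice-to-physical spatial scale
#'
#' Adjusts the plateau level of the model mean-square-distance curve to that
#' of an experimental (or synthetic) FISH curve:
#' `nm_per_lattice_unit = sqrt(plateau_exp / plateau_model) * 1000`, with
#' each plateau estimated as the mean over the top quartile of genomic
#' separations (restricted to the overlapping genomic range).  The model
#' curve must exhibit a plateau -- relative drift below 5% across the top
#' quartile -- unless `force = TRUE` requests plain least-squares scaling of
#' the overlapping points.
#'
#' @param model_curve `dl_msd_curve` in lattice units squared.
#' @param fish_curve `dl_msd_curve` in um^2.
#' @param kb_per_bead Genomic content of one bead (kb), recorded in the
#'   mapping.
#' @param force Skip the plateau check and scale by least squares.
#' @return A `dl_unit_mapping`: list with `nm_per_lattice_unit`,
#'   `kb_per_bead`, `nm_per_bead` (using the ensemble mean bond length when
#'   given in `attr(model_curve, "mean_bond_length")`), plateau estimates and
#'   residual diagnostics.
#' @export
dl_fit_spatial_scale <- function(model_curve, fish_curve, kb_per_bead = 400,
                                 force = FALSE) {
  lo <- max(min(model_curve$genomic_kb), min(fish_curve$genomic_kb))
  hi <- min(max(model_curve$genomic_kb), max(fish_curve$genomic_kb))
  if (lo >= hi) stop("model and experimental curves do not overlap in genomic range")
  mc <- model_curve[model_curve$genomic_kb >= lo & model_curve$genomic_kb <= hi, ]
  fc <- fish_curve[fish_curve$genomic_kb >= lo & fish_curve$genomic_kb <= hi, ]

  top <- function(curve) {
    q <- stats::quantile(curve$genomic_kb, 0.75)
    curve[curve$genomic_kb >= q, , drop = FALSE]
  }
  mtop <- top(mc)
  drift <- if (nrow(mtop) >= 3) {
    fit <- stats::lm(msd ~ genomic_kb, data = mtop)
    abs(stats::coef(fit)[2] * diff(range(mtop$genomic_kb))) / mean(mtop$msd)
  } else NA_real_
  has_plateau <- !is.na(drift) && drift < 0.05

  if (!has_plateau && !force)
    stop("model curve has no plateau (relative drift ",
         format(drift, digits = 3),
         " over the top quartile); use force = TRUE for least-squares scaling")

  if (has_plateau && !force) {
    plateau_model <- mean(mtop$msd)
    plateau_exp <- mean(top(fc)$msd)
    scale2 <- plateau_exp / plateau_model   # um^2 per lattice-unit^2
  } else {
    m_on_f <- stats::approx(mc$genomic_kb, mc$msd, xout = fc$genomic_kb,
                            rule = 2)$y
    scale2 <- sum(fc$msd * m_on_f) / sum(m_on_f^2)
    plateau_model <- mean(top(mc)$msd)
    plateau_exp <- plateau_model * scale2
  }
  nm_per_lu <- sqrt(scale2) * 1000
  mbl <- attr(model_curve, "mean_bond_length")
  resid <- {
    m_on_f <- stats::approx(mc$genomic_kb, mc$msd * scale2,
                            xout = fc$genomic_kb, rule = 2)$y
    fc$msd - m_on_f
  }
  structure(list(nm_per_lattice_unit = nm_per_lu,
                 kb_per_bead = kb_per_bead,
                 nm_per_bead = if (!is.null(mbl)) mbl * nm_per_lu else NA_real_,
                 plateau_model_lu2 = plateau_model,
                 plateau_exp_um2 = plateau_exp,
                 plateau_drift = unname(drift),
                 method = if (has_plateau && !force) "plateau" else "least-squares",
                 rmse_um2 = sqrt(mean(resid^2))),
            class = "dl_unit_mapping")
}

#' @export
print.dl_unit_mapping <- function(x, ...) {
  cat("Lattice-to-physical unit mapping (", x$method, " matching)\n", sep = "")
  cat("  ", format(x$nm_per_lattice_unit, digits = 4), "nm per lattice unit;",
      x$kb_per_bead, "kb per bead")
  if (!is.na(x$nm_per_bead))
    cat(";", format(x$nm_per_bead, digits = 4), "nm per bead")
  cat("\n  plateaus: model", format(x$plateau_model_lu2, digits = 4),
      "lu^2, experimental", format(x$plateau_exp_um2, digits = 4), "um^2\n")
  invisible(x)
}

#' Radius of gyration implied by an internal mean-square-distance curve
#'
#' For any chain, `R_g^2 = (1/2N^2) sum_{i,j} MSD(|i - j|)`.  Given a
#' measured `MSD(s)` curve this identity reconstructs `R_g^2` for a chain of
#' `n_beads` monomers; lags beyond the measured range are extended with the
#' curve's top-quartile mean (its plateau) when it levels off, or with a
#' power-law fit of the top half otherwise.  Used to transfer separations
#' expressed in units of `R_g` between chain lengths without re-simulating:
#' the internal distance statistics of the looping phase are set by the
#' per-monomer loop density, so the measured curve at one `N` predicts the
#' coil size at a nearby `N`.
#'
#' @param curve `dl_msd_curve` with `msd` in lattice units squared.
#' @param n_beads Chain length to evaluate.
#' @param kb_per_bead Genomic content per bead used in `curve`.
#' @return `rg2` in lattice units squared.
#' @export
dl_rg2_from_msd <- function(curve, n_beads, kb_per_bead = 400) {
  s <- round(curve$genomic_kb / kb_per_bead)
  msd <- curve$msd[order(s)]
  s <- sort(s)
  if (any(s < 1) || any(duplicated(s))) stop("curve must have integer lags >= 1")
  smax <- max(s)
  msd_all <- stats::approx(s, msd, xout = seq_len(min(smax, n_beads - 1)))$y
  if (n_beads - 1 > smax) {
    top <- s >= stats::quantile(s, 0.75)
    df <- data.frame(ls = log(s[top]), lm = log(msd[top]))
    fit <- stats::lm(lm ~ ls, data = df)
    expo <- stats::coef(fit)[2]
    ext <- if (abs(expo) < 0.1) {
      rep(mean(msd[top]), n_beads - 1 - smax)   # leveled off: plateau
    } else {
      exp(unname(stats::predict(
        fit, newdata = data.frame(ls = log((smax + 1):(n_beads - 1))))))
    }
    msd_all <- c(msd_all, ext)
  }
  # sum over ordered pairs: each lag s occurs 2 (N - s) times among N^2 pairs
  sum(2 * (n_beads - seq_len(n_beads - 1)) * msd_all) / (2 * n_beads^2)
}

#' Convert a physical distance to lattice units
#'
#' @param um Distance in micrometers.
#' @param mapping `dl_unit_mapping`, or a number of nm per lattice unit.
#' @export
dl_um_to_lattice <- function(um, mapping) {
  nm <- if (inherits(mapping, "dl_unit_mapping")) mapping$nm_per_lattice_unit
        else as.numeric(mapping)
  um * 1000 / nm
}
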