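# Plain-text persistence: conformations as extended-XYZ-like files, loop
# event logs and observable tables as TSV, run manifests as JSON.

#' Write one conformation to an extended-XYZ-like text file
#'
#' Line 1: N.  Line 2: a comment carrying `seed=... sweep=...`.  Then one
#' integer triple per line.
#'
#' @param positions N x 3 integer matrix.
#' @param path Output file.
#' @param seed,sweep Metadata recorded in the header comment.
#' @export
dl_write_conformation <- function(positions, path, seed = NA, sweep = NA) {
  positions <- as_positions(positions)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(as.character(nrow(positions)),
               paste0("# dlchrom conformation seed=", seed, " sweep=", sweep)),
             con)
  utils::write.table(positions, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a conformation written by [dl_write_conformation()]
#' @param path Input file.
#' @return N x 3 integer matrix with attributes `seed` and `sweep`.
#' @export
dl_read_conformation <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("malformed conformation file (", path,
                               "): fewer than 2 header lines")
  n <- suppressWarnings(as.integer(lines[1L]))
  if (is.na(n)) stop("malformed conformation file (", path, "): line 1 is not N")
  hdr <- lines[2L]
  body <- utils::read.table(text = lines[3:(2L + n)])
  pos <- as_positions(as.matrix(body))
  colnames(pos) <- c("x", "y", "z")
  grab <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "=[^ ]+"), hdr))
    if (!length(m)) return(NA)
    sub(paste0(key, "="), "", m)
  }
  attr(pos, "seed") <- grab("seed")
  attr(pos, "sweep") <- suppressWarnings(as.integer(grab("sweep")))
  pos
}

#' Persist an ensemble to a directory
#'
#' Writes one conformation file per snapshot (`conf_0001.xyz`, ...), an
#' `observables.tsv` series table, and a `manifest.json` with all parameters,
#' diagnostics and the package version, sufficient to re-run the job
#' bit-identically.
#'
#' @param ensemble `dl_ensemble` from [dl_simulate()].
#' @param dir Output directory (created if missing).
#' @export
dl_write_ensemble <- function(ensemble, dir) {
  stopifnot(inherits(ensemble, "dl_ensemble"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_along(ensemble$conformations))
    dl_write_conformation(ensemble$conformations[[k]],
                          file.path(dir, sprintf("conf_%04d.xyz", k)),
                          seed = ensemble$params$seed,
                          sweep = ensemble$kept_at[k])
  obs <- data.frame(sweep = ensemble$series$sweep, rg2 = ensemble$series$rg2,
                    loop_count = ensemble$series$loop_count,
                    acceptance = ensemble$series$acceptance)
  utils::write.table(obs, file.path(dir, "observables.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  manifest <- c(ensemble$params,
                list(n_conformations = length(ensemble$conformations),
                     kept_at = ensemble$kept_at,
                     tau_int = ensemble$tau_int, tau_saw = ensemble$tau_saw,
                     spacing = ensemble$spacing, burn_in = ensemble$burn_in,
                     mean_loop_count = ensemble$mean_loop_count,
                     rg_iso = ensemble$rg_iso, rg2_iso = ensemble$rg2_iso,
                     asph_iso = ensemble$asph_iso,
                     mean_bond_length = ensemble$mean_bond_length,
                     package_version = as.character(utils::packageVersion("dlchrom"))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read an ensemble directory written by [dl_write_ensemble()]
#' @param dir Ensemble directory.
#' @return A `dl_ensemble` (without the raw series' acceptance history if the
#'   observables table was removed).
#' @export
dl_read_ensemble <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^conf_\\d+\\.xyz$", full.names = TRUE))
  if (!length(files)) stop("no conformation files in ", dir)
  confs <- lapply(files, dl_read_conformation)
  series <- NULL
  obs <- file.path(dir, "observables.tsv")
  if (file.exists(obs)) {
    tab <- utils::read.table(obs, header = TRUE, sep = "\t")
    series <- as.list(tab)
  }
  structure(list(conformations = confs, kept_at = manifest$kept_at,
                 series = series,
                 params = manifest[c("N", "p", "lifetime_multiplier",
                                     "lifetime_mean", "coloc_threshold", "seed",
                                     "saw_sweeps", "production_sweeps",
                                     "store_every", "record_every")],
                 tau_saw = manifest$tau_saw, tau_int = manifest$tau_int,
                 spacing = manifest$spacing, burn_in = manifest$burn_in,
                 mean_loop_count = manifest$mean_loop_count,
                 rg_iso = manifest$rg_iso, rg2_iso = manifest$rg2_iso,
                 asph_iso = manifest$asph_iso,
                 mean_bond_length = manifest$mean_bond_length),
            class = "dl_ensemble")
}

#' Write / read a tab-separated table
#'
#' Round-trip helpers used for potential curves, shape profiles, MSD curves
#' and loop-event logs.
#' @param x Data frame.
#' @param path File path.
#' @export
dl_write_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname dl_write_tsv
#' @export
dl_read_tsv <- function(path) {
  if (!file.size(path) > 0) stop("empty file: ", path, " (line 1)")
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Read a two-column FISH distance table
#'
#' Plain-text delimited columns: genomic separation (kb) and mean square
#' spatial distance (um^2), with a one-line header.
#'
#' @param path File path.
#' @return A `dl_msd_curve` with `source = basename(path)`.
#' @export
dl_read_fish_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (!file.size(path) > 0) stop("empty FISH table: ", path, " (line 1)")
  tab <- utils::read.table(path, header = TRUE)
  if (ncol(tab) < 2L) stop("FISH table needs two columns (line 1 of ", path, ")")
  out <- data.frame(genomic_kb = tab[[1]], msd = tab[[2]],
                    source = basename(path), stringsAsFactors = FALSE)
  if (any(diff(out$genomic_kb) <= 0))
    stop("genomic separations must be strictly increasing in ", path)
  if (any(out$msd < 0)) stop("negative mean square distances in ", path)
  class(out) <- c("dl_msd_curve", class(out))
  out
}
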