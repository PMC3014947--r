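# Run configuration: a YAML key-value file with a fixed schema.
# Unknown keys are errors (fail-fast), and a parsed config round-trips
# through serialization losslessly.

config_schema <- list(
  N = list(check = function(v) v >= 1, msg = "N must be >= 1"),
  p = list(check = function(v) v >= 0 && v <= 1, msg = "p must be in [0, 1]"),
  lifetime_multiplier = list(check = function(v) v > 0,
                             msg = "lifetime_multiplier must be positive"),
  lifetime_mean = list(optional = TRUE, check = function(v) v > 0,
                       msg = "lifetime_mean must be positive"),
  equilibration_sweeps = list(optional = TRUE, check = function(v) v >= 1,
                              msg = "equilibration_sweeps must be positive"),
  production_sweeps = list(optional = TRUE, check = function(v) v >= 1,
                           msg = "production_sweeps must be positive"),
  n_conformations = list(optional = TRUE, check = function(v) v >= 1,
                         msg = "n_conformations must be positive"),
  store_every = list(optional = TRUE, check = function(v) v >= 1,
                     msg = "store_every must be positive"),
  record_every = list(optional = TRUE, check = function(v) v >= 1,
                      msg = "record_every must be positive"),
  seed = list(check = function(v) v == round(v), msg = "seed must be integer"),
  coloc_threshold = list(optional = TRUE, check = function(v) v > 0,
                         msg = "coloc_threshold must be positive"),
  r_grid = list(optional = TRUE, check = function(v) all(v >= 0),
                msg = "r_grid values must be >= 0"),
  trials_per_bin = list(optional = TRUE, check = function(v) v >= 1,
                        msg = "trials_per_bin must be positive"),
  kb_per_bead = list(optional = TRUE, check = function(v) v > 0,
                     msg = "kb_per_bead must be positive"),
  nm_per_lattice_unit = list(optional = TRUE, check = function(v) v > 0,
                             msg = "nm_per_lattice_unit must be positive"),
  output_dir = list(optional = TRUE, check = is.character,
                    msg = "output_dir must be a path")
)

#' Read and validate a run configuration
#'
#' YAML key-value file mirroring the [dl_simulate()] /
#' [dl_estimate_potential()] parameters.  Unknown keys are an error;
#' constraint violations name the offending key.
#'
#' @param path YAML file.
#' @return A validated `dl_config` list.
#' @export
dl_read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  raw <- yaml::read_yaml(path)
  dl_validate_config(raw)
}

#' @rdname dl_read_config
#' @param config A named list of configuration values.
#' @export
dl_validate_config <- function(config) {
  if (!is.list(config) || is.null(names(config)))
    stop("config must be a named key-value mapping")
  unknown <- setdiff(names(config), names(config_schema))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (key in names(config_schema)) {
    spec <- config_schema[[key]]
    if (is.null(config[[key]])) {
      if (!isTRUE(spec$optional)) stop("missing required config key: ", key)
      next
    }
    v <- config[[key]]
    if (!all(vapply(list(v), function(z) isTRUE(all(spec$check(z))), logical(1))))
      stop("invalid value for ", key, ": ", spec$msg)
  }
  structure(config, class = "dl_config")
}

#' Write a configuration back to YAML
#' @param config `dl_config` list.
#' @param path Output file.
#' @export
dl_write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
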