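#' Validated run configuration
#'
#' Collects every pipeline parameter with its documented default, validates
#' ranges at load time, and names the offending parameter on failure.
#' Values can be supplied as a named list or a YAML file.
#'
#' Defaults: `dmax = 15` (voxel widths), `stop_fraction = 0.2`,
#' `seed_threshold = 0.3`, `seed_min_separation = 10`, `smoothing_sigma =
#' 1`, `cluster_threshold = 10`, `kappa = 1`, `C = 2^20`, `T_conf = 1`,
#' `d = 0.25`, `h = 10`, `min_terminal_len = 12`, `min_intensity = 0.12`,
#' `alpha_r = 1`, `alpha_R = 1`, `beta = 0.5`, `rng_seed = 1`,
#' `verbosity = 1`.
#'
#' @param config named list of overrides, or a path to a YAML file.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    dmax = 15, stop_fraction = 0.2, seed_threshold = 0.3,
    seed_min_separation = 10, smoothing_sigma = 1, cluster_threshold = 10,
    kappa = 1, C = 2^20, T_conf = 1, d = 0.25, h = 10,
    min_terminal_len = 12, min_intensity = 0.12,
    alpha_r = 1, alpha_R = 1, beta = 0.5, rng_seed = 1L, verbosity = 1L)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0)
    stop("unknown config parameter(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  chk <- function(name, ok)
    if (!isTRUE(ok)) stop(sprintf("config parameter '%s' out of range", name))
  chk("dmax", cfg$dmax > 0)
  chk("stop_fraction", cfg$stop_fraction >= 0 && cfg$stop_fraction < 1)
  chk("seed_threshold", cfg$seed_threshold > 0 && cfg$seed_threshold < 1)
  chk("seed_min_separation", cfg$seed_min_separation > 0)
  chk("smoothing_sigma", cfg$smoothing_sigma >= 0)
  chk("cluster_threshold", cfg$cluster_threshold > 0)
  chk("kappa", cfg$kappa >= 0)
  chk("C", cfg$C > 0)
  chk("T_conf", cfg$T_conf > 0)
  chk("d", cfg$d > 0)
  chk("h", cfg$h > 0)
  chk("min_terminal_len", cfg$min_terminal_len >= 0)
  chk("min_intensity", cfg$min_intensity >= 0 && cfg$min_intensity < 1)
  chk("alpha_r", cfg$alpha_r > 0)
  chk("alpha_R", cfg$alpha_R > 0)
  chk("beta", cfg$beta > 0)
  structure(cfg, class = "run_config")
}

#' Provenance block for machine-readable reports
#'
#' @param config a [run_config()].
#' @return Named list with package version, a hash of the configuration,
#'   and the seed, suitable for embedding in JSON outputs.
#' @export
provenance <- function(config) {
  cfgtxt <- paste(names(config), unlist(config), sep = "=", collapse = ";")
  list(package = "neuritrace",
       version = as.character(utils::packageVersion("neuritrace")),
       config_hash = sprintf("%08x", sum(utf8ToInt(cfgtxt) *
                                           seq_along(utf8ToInt(cfgtxt)))),
       rng_seed = config$rng_seed)
}
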