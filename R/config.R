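#' Read, validate and resolve a run configuration
#'
#' A run configuration is a YAML document with up to five sections --
#' `landscape`, `simulation`, `pulling`, `umbrella`, `analysis` -- binding
#' the parameters of a whole pipeline run. Unknown section names or unknown
#' keys within a section are rejected (typos must not silently fall back to
#' defaults), and the resolved copy has every default materialised so an
#' emitted config reproduces the run exactly.
#'
#' @param path Path to a YAML file.
#' @return A named list of class `run_config` with all defaults filled in.
#' @seealso [write_run_config()]
#' @export
read_run_config <- function(path) {
  resolve_run_config(yaml::read_yaml(path))
}

config_schema <- list(
  landscape = c("preset", "species_label", "axial_features", "lateral_k",
                "pair_amplitude", "pair_screening", "coordination_features"),
  simulation = c("temperature", "diffusion", "timestep", "seed",
                 "recording_interval", "noise_enabled", "z_bounds"),
  pulling = c("direction", "n_ions", "k_axial", "k_lateral", "lambda_start",
              "lambda_increment", "n_steps", "tau", "xy_center", "n_replicas",
              "recording_interval", "seed"),
  umbrella = c("ranges", "spacing", "k_umb", "grid_bin", "n_frames",
               "burn_in"),
  analysis = c("bin_width", "delta_diag", "theta_occ", "filter_span",
               "block_region"))

#' @rdname read_run_config
#' @param config A named list (parsed YAML) to validate and resolve.
#' @export
resolve_run_config <- function(config) {
  stopifnot(is.list(config))
  bad <- setdiff(names(config), names(config_schema))
  if (length(bad) > 0)
    stop("unknown config section(s): ", paste(bad, collapse = ", "))
  for (sec in names(config)) {
    unknown <- setdiff(names(config[[sec]]), config_schema[[sec]])
    if (length(unknown) > 0)
      stop("unknown key(s) in section '", sec, "': ",
           paste(unknown, collapse = ", "))
  }
  defaults <- list(
    landscape = list(preset = "K-like"),
    simulation = list(temperature = 300, diffusion = 0.2, timestep = 0.002,
                      seed = 1L, recording_interval = 1,
                      noise_enabled = TRUE, z_bounds = NULL),
    pulling = list(direction = "inward", n_ions = 2, k_axial = 0.6,
                   k_lateral = 0.6, tau = 300, n_replicas = 20, seed = 1L),
    umbrella = list(spacing = 0.5, k_umb = 10, grid_bin = 0.5,
                    n_frames = 2e4, burn_in = 0.1),
    analysis = list(bin_width = 0.5, delta_diag = 1.0, theta_occ = 0.2,
                    filter_span = c(-15, -5), block_region = c(-15, -10)))
  out <- defaults
  for (sec in names(config)) out[[sec]] <- utils::modifyList(
    defaults[[sec]], config[[sec]], keep.null = TRUE)
  structure(out, class = "run_config")
}

#' Write a fully resolved run configuration
#'
#' @param config A `run_config` (or plain list, resolved first).
#' @param path Output YAML path.
#' @return The path, invisibly.
#' @export
write_run_config <- function(config, path) {
  if (!inherits(config, "run_config")) config <- resolve_run_config(config)
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
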