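#' Pulling-protocol presets for the shipped landscapes
#'
#' Mirrors the two step-wise protocols used throughout the analysis: an
#' inward pull advancing the restraint centre by +1.0 A per step from -20 to
#' -2 A (19 centres), starting with one ion at the filter entrance
#' (z = -15) and the rest at z = -20; and an outward pull from 4.5 to
#' -17.5 A (23 centres) starting from a relaxed single-file configuration on
#' the cavity side. The default relaxation time of 300 ps is the "slow"
#' protocol in simulator time units; 50 ps is the "fast" one (the all-atom
#' originals are 3 ns and 0.5 ns; one global factor of 0.1 maps them onto
#' the Brownian clock, whose in-well relaxation times are ~1 ps).
#'
#' @param direction "inward" or "outward".
#' @param n_ions 1, 2 or 3 pulled ions.
#' @param tau Relaxation time per step, ps (300 = slow, 50 = fast).
#' @param n_replicas Number of replicas.
#' @param k_axial Spring constant, kcal/mol/A^2 (soft, 0.6, by default).
#' @param seed Master seed.
#' @return A [pull_spec()].
#' @export
preset_pull <- function(direction = c("inward", "outward"), n_ions = 2,
                        tau = 300, n_replicas = 20, k_axial = 0.6,
                        seed = 1L) {
  direction <- match.arg(direction)
  stopifnot(n_ions %in% 1:3)
  if (direction == "inward") {
    z0 <- list(-20, c(-15, -20), c(-15, -20, -20))[[n_ions]]
    pull_spec(k_axial = k_axial, lambda_start = -20, lambda_increment = 1,
              n_steps = 19, tau = tau, n_replicas = n_replicas,
              initial_placement = data.frame(x = 0, y = 0, z = z0),
              seed = seed)
  } else {
    z0 <- list(4.5, c(4.5, 1.5), c(4.5, 1.5, -1.5))[[n_ions]]
    pull_spec(k_axial = k_axial, lambda_start = 4.5, lambda_increment = -1,
              n_steps = 23, tau = tau, n_replicas = n_replicas,
              initial_placement = data.frame(x = 0, y = 0, z = z0),
              seed = seed)
  }
}

#' Simulator configuration suited to the shipped presets
#'
#' The K-like preset's coordination terms have local stiffness up to about
#' 130 kcal/mol/A^2, so the integrator needs dt of 2 fs or less to satisfy
#' the stability bound (k D dt / k_B T < 0.1); biased umbrella sampling on
#' top of it needs a little less still.
#'
#' @param seed Master seed.
#' @param timestep Integration step, ps.
#' @param recording_interval Frame recording interval, ps.
#' @return A [sim_config()].
#' @export
preset_sim_config <- function(seed = 1L, timestep = 0.002,
                              recording_interval = 1) {
  sim_config(seed = seed, timestep = timestep,
             recording_interval = recording_interval)
}
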