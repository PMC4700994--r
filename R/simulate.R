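#' Configure the Brownian simulator
#'
#' Parameters of the overdamped Langevin (Euler-Maruyama) integrator that
#' stands in for all-atom dynamics: each coordinate advances by
#' (D/k_B T) F dt plus, when noise is enabled, a Gaussian increment of
#' variance 2 D dt. There is no inertia; ion motion in a narrow filter is
#' diffusive on the timescales analysed here.
#'
#' @param temperature Temperature, K (default 300).
#' @param diffusion Diffusion constant D, A^2/ps. Either a single value or a
#'   named vector by species tag. The default 0.2 A^2/ps is of the order of
#'   bulk ion diffusivity; no measured in-filter value exists, so treat it as
#'   an effective parameter.
#' @param timestep Integration step dt, ps.
#' @param seed Integer master seed; per-replica streams are derived from it
#'   (see Details).
#' @param recording_interval Interval between recorded frames, ps (>=
#'   timestep).
#' @param noise_enabled If FALSE the dynamics is deterministic drift only
#'   (test mode).
#' @param z_bounds Optional length-2 vector of reflecting walls on z, A.
#'
#' @details Replica streams are derived from the master seed by a fixed
#' counter scheme, `seed_stream(seed, replica)`, so a replica's trajectory
#' does not depend on how many other replicas run or in what order.
#'
#' The integrator is stable only if k_max D dt / k_B T < 0.1 for the largest
#' stiffness k_max in play (landscape curvature plus any bias spring);
#' running functions check this bound and refuse to start when it is
#' violated.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(temperature = 300, diffusion = 0.2, timestep = 0.01,
                       seed = 1L, recording_interval = 0.1,
                       noise_enabled = TRUE, z_bounds = NULL) {
  stopifnot(temperature > 0, all(diffusion > 0), timestep > 0)
  if (recording_interval < timestep)
    stop("`recording_interval` must be >= `timestep`")
  if (!is.null(z_bounds)) {
    stopifnot(length(z_bounds) == 2, z_bounds[1] < z_bounds[2])
  }
  structure(list(temperature = temperature, diffusion = diffusion,
                 timestep = timestep, seed = as.integer(seed),
                 recording_interval = recording_interval,
                 noise_enabled = isTRUE(noise_enabled), z_bounds = z_bounds),
            class = "sim_config")
}

kbt <- function(config) constants$k_B * config$temperature

diffusion_for <- function(config, species) {
  d <- config$diffusion
  if (is.null(names(d))) return(rep(d[1], length(species)))
  miss <- setdiff(unique(species), names(d))
  if (length(miss) > 0) stop("no diffusion constant for species: ",
                             paste(miss, collapse = ", "))
  unname(d[species])
}

#' Derive an independent seed stream for a replica
#'
#' Fixed counter-based mapping from (master seed, replica index) to a
#' substream seed, kept below 2^31. Identical inputs give identical streams;
#' replica sets are order-independent.
#'
#' @param seed Master seed (integer).
#' @param replica Replica counter (integer >= 0).
#' @return An integer seed.
#' @export
seed_stream <- function(seed, replica) {
  as.integer((as.double(seed) * 2654435761 + as.double(replica) * 40503) %%
               2147483647)
}

check_stability <- function(k_max, config) {
  bound <- k_max * max(config$diffusion) * config$timestep / kbt(config)
  if (bound >= 0.1)
    stop(sprintf(paste0("integrator stability bound violated: ",
                        "k_max*D*dt/kBT = %.3f >= 0.1; reduce the timestep"),
                 bound))
  invisible(bound)
}

#' Advance one Brownian step
#'
#' Single Euler-Maruyama update under an externally supplied force, exposed
#' mainly for testing the update rule; long runs go through
#' [simulate_trajectory()], which shares the same compiled kernel.
#'
#' @param positions Data frame/matrix with columns x, y, z (one row per ion).
#' @param config A [sim_config()].
#' @param force n x 3 matrix of forces, kcal/mol/A.
#' @param species Optional species tags (for per-species diffusion).
#' @return Updated position matrix.
#' @export
step_overdamped <- function(positions, config, force,
                            species = rep("ion", nrow(pos))) {
  pos <- as_position_matrix(positions)
  force <- as.matrix(force)
  if (any(!is.finite(force)))
    stop("force propagation error: non-finite force on ion ",
         which(!is.finite(rowSums(force)))[1])
  D <- diffusion_for(config, species)
  mob <- D * config$timestep / kbt(config)
  out <- pos + force * mob
  if (config$noise_enabled) {
    out <- out + matrix(stats::rnorm(length(pos), sd = sqrt(2 * D * config$timestep)),
                        ncol = 3)
  }
  if (!is.null(config$z_bounds)) out[, 3] <- reflect(out[, 3], config$z_bounds)
  out
}

reflect <- function(z, bounds) {
  lo <- bounds[1]; hi <- bounds[2]
  repeat {
    below <- z < lo; above <- z > hi
    if (!any(below) && !any(above)) return(z)
    z[below] <- 2 * lo - z[below]
    z[above] <- 2 * hi - z[above]
  }
}

# Core driver: biased/unbiased Brownian run on a landscape.
# bias_k/bias_center are n x 3 matrices (0 = unbiased coordinate).
# Returns list(frames = tibble(time, ion, species, x, y, z), final = matrix).
run_brownian <- function(spec, config, positions, species, n_steps, seed,
                         bias_k = NULL, bias_center = NULL,
                         record_stride = NULL, t0 = 0) {
  pos <- as_position_matrix(positions)
  n <- nrow(pos)
  if (is.null(bias_k)) bias_k <- matrix(0, n, 3)
  if (is.null(bias_center)) bias_center <- matrix(0, n, 3)
  check_stability(landscape_stiffness(spec) + max(bias_k), config)
  if (is.null(record_stride))
    record_stride <- max(1L, round(config$recording_interval / config$timestep))
  zb <- if (is.null(config$z_bounds)) c(-Inf, Inf) else config$z_bounds
  out <- .simulate_cpp(pos, ls_params(spec), diffusion_for(config, species),
                       config$timestep, as.integer(n_steps),
                       as.integer(record_stride), kbt(config),
                       config$noise_enabled, as.double(seed),
                       bias_k, bias_center, zb[1], zb[2])
  nrec <- dim(out$frames)[1]
  frames <- NULL
  if (nrec > 0) {
    tt <- t0 + seq_len(nrec) * record_stride * config$timestep
    frames <- tibble::tibble(
      time = rep(tt, times = n),
      ion = rep(seq_len(n), each = nrec),
      species = rep(species, each = nrec),
      x = as.vector(out$frames[, 1, ]),
      y = as.vector(out$frames[, 2, ]),
      z = as.vector(out$frames[, 3, ]))
    frames <- dplyr::arrange(frames, .data$time, .data$ion)
  }
  list(frames = frames, final = out$final)
}

#' Sample the equilibrium axial distribution of one ion
#'
#' Runs unbiased Brownian dynamics on a landscape and histograms the axial
#' coordinate. Up to an additive constant, -k_B T log(histogram) reproduces
#' the axial potential U0(z); this is the simulator's Boltzmann validation.
#'
#' @param spec A [landscape_spec()].
#' @param config A [sim_config()]; set `z_bounds` to keep the ion on a
#'   bounded interval.
#' @param n_frames Number of recorded frames (>= 1000).
#' @param bin_width Histogram bin width, A.
#' @param burn_in Fraction of frames discarded from the start (default 0.1).
#' @param z0 Starting axial position (default: centre of `z_bounds`).
#' @param species Species tag used for the diffusion lookup.
#' @return A tibble with columns `z` (bin mid), `count`, and `f_est`
#'   (-k_B T log count, offset to min 0 over sampled bins).
#' @export
sample_equilibrium <- function(spec, config, n_frames, bin_width = 0.25,
                               burn_in = 0.1, z0 = NULL, species = "ion") {
  if (n_frames < 1000)
    stop("n_frames < 1000: too few frames for a meaningful equilibrium ",
         "histogram; use at least 1e3 (1e5-1e6 for quantitative recovery)")
  if (is.null(config$z_bounds))
    stop("set `z_bounds` in the config: unbounded diffusion has no ",
         "normalisable equilibrium distribution")
  if (is.null(z0)) z0 <- mean(config$z_bounds)
  stride <- max(1L, round(config$recording_interval / config$timestep))
  run <- run_brownian(spec, config, cbind(0, 0, z0), species,
                      n_steps = n_frames * stride, seed = config$seed,
                      record_stride = stride)
  z <- run$frames$z
  z <- z[-seq_len(floor(burn_in * length(z)))]
  breaks <- seq(config$z_bounds[1], config$z_bounds[2], by = bin_width)
  if (max(breaks) < config$z_bounds[2])
    breaks <- c(breaks, config$z_bounds[2])
  h <- graphics::hist(z, breaks = breaks, plot = FALSE)
  keep <- h$counts > 0
  f <- rep(NA_real_, length(h$counts))
  f[keep] <- -kbt(config) * log(h$counts[keep])
  f <- f - min(f, na.rm = TRUE)
  tibble::tibble(z = h$mids, count = h$counts, f_est = f)
}

#' Generate uniform solvent points in a cylinder
#'
#' Synthetic "water oxygen" coordinates used by the shared-solvent counter:
#' a Poisson number of points (mean density * volume) placed uniformly in a
#' cylinder aligned with the pore axis.
#'
#' @param radius Cylinder radius, A (> 0).
#' @param z_range Length-2 axial extent, A.
#' @param density Points per A^3 (>= 0); bulk water is about 0.033/A^3.
#' @param seed Integer seed.
#' @return A tibble with columns x, y, z.
#' @export
generate_solvent_points <- function(radius, z_range, density, seed = 1L) {
  if (radius <= 0) stop("`radius` must be > 0")
  stopifnot(length(z_range) == 2, z_range[1] < z_range[2], density >= 0)
  vol <- pi * radius^2 * diff(z_range)
  n <- withr::with_seed(seed, stats::rpois(1, density * vol))
  withr::with_seed(seed + 1L, {
    r <- radius * sqrt(stats::runif(n))
    th <- stats::runif(n, 0, 2 * pi)
    tibble::tibble(x = r * cos(th), y = r * sin(th),
                   z = stats::runif(n, z_range[1], z_range[2]))
  })
}
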