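#' Specify a step-wise pulling protocol
#'
#' Ions are held by independent harmonic restraints
#' U(x,y,z; lambda) = 0.5 k_l (x - x0)^2 + 0.5 k_l (y - y0)^2 +
#' 0.5 k (z - lambda)^2 whose axial centre lambda advances in discrete
#' increments; after each increment the system relaxes for a time tau before
#' the next switch. The work of each instantaneous switch, evaluated at the
#' frozen coordinates, accumulates into the Jarzynski work ledger.
#'
#' @param k_axial Axial spring constant k, kcal/mol/A^2 (> 0). A soft spring
#'   (0.6-1) probes forces of membrane-potential magnitude; a stiff one
#'   (>> 1) recovers the unperturbed PMF.
#' @param k_lateral Lateral spring constant, kcal/mol/A^2.
#' @param lambda_start First restraint centre, A.
#' @param lambda_increment Signed increment, A (+ = inward).
#' @param n_steps Number of schedule entries (centres), >= 1.
#' @param tau Relaxation time per step, ps.
#' @param xy_center Lateral restraint centre (x0, y0), A.
#' @param n_replicas Number of independent replicas.
#' @param recording_interval Frame recording interval, ps.
#' @param initial_placement Data frame with columns x, y, z (one row per
#'   ion): starting coordinates. The shipped three-ion preset places one ion
#'   at z = -15 and two at z = -20.
#' @param seed Integer master seed.
#' @return An object of class `pull_spec`.
#' @export
pull_spec <- function(k_axial = 0.6, k_lateral = k_axial, lambda_start = -20,
                      lambda_increment = 1, n_steps = 19, tau = 50,
                      xy_center = c(0, 0), n_replicas = 20,
                      recording_interval = 1,
                      initial_placement = data.frame(x = 0, y = 0, z = -20),
                      seed = 1L) {
  stopifnot(n_steps >= 1, tau > 0, k_axial > 0, k_lateral >= 0,
            length(xy_center) == 2, n_replicas >= 1)
  if (lambda_increment == 0 && n_steps > 1)
    stop("zero `lambda_increment` with more than one step")
  structure(list(k_axial = k_axial, k_lateral = k_lateral,
                 lambda_start = lambda_start,
                 lambda_increment = lambda_increment,
                 n_steps = as.integer(n_steps), tau = tau,
                 xy_center = xy_center, n_replicas = as.integer(n_replicas),
                 recording_interval = recording_interval,
                 initial_placement = as.data.frame(initial_placement),
                 seed = as.integer(seed)),
            class = "pull_spec")
}

#' Three-ion starting placement at the extracellular entrance
#'
#' One ion at z = -15 (the filter entrance) and two at z = -20, mimicking an
#' ion gradient feeding the filter from the extracellular side.
#' @return A data frame with columns x, y, z.
#' @export
placement_three_ion <- function() {
  data.frame(x = c(0, 0, 0), y = c(0, 0, 0), z = c(-15, -20, -20))
}

#' Build the ordered restraint-centre schedule
#'
#' lambda_i = lambda_start + i * lambda_increment for i = 0 .. n_steps - 1.
#' The shipped inward protocol advances by 1.0 A from -20 to -2 A (19
#' centres); the outward one from 4.5 to -17.5 A (23 centres).
#'
#' @param spec A [pull_spec()].
#' @return Numeric vector of lambda centres, A.
#' @export
#' @examples
#' build_schedule(pull_spec(lambda_start = -20, lambda_increment = 1,
#'                          n_steps = 19))
build_schedule <- function(spec) {
  stopifnot(inherits(spec, "pull_spec"))
  spec$lambda_start + (seq_len(spec$n_steps) - 1) * spec$lambda_increment
}

#' Harmonic restraint energy at one position
#'
#' @param position Length-3 numeric (x, y, z), A.
#' @param lambda Axial restraint centre, A.
#' @param spec A [pull_spec()].
#' @return Energy in kcal/mol (0 iff the ion sits exactly at
#'   (x0, y0, lambda)).
#' @export
restraint_energy <- function(position, lambda, spec) {
  stopifnot(all(is.finite(position)), length(position) == 3)
  0.5 * spec$k_lateral * (position[1] - spec$xy_center[1])^2 +
    0.5 * spec$k_lateral * (position[2] - spec$xy_center[2])^2 +
    0.5 * spec$k_axial * (position[3] - lambda)^2
}

#' Work of an instantaneous restraint switch
#'
#' With coordinates frozen at the switch instant, moving the axial centre
#' from lambda_i to lambda_next changes only the axial restraint term, so
#' dW = sum over ions of 0.5 k [(z - lambda_next)^2 - (z - lambda_i)^2];
#' the lateral terms cancel.
#'
#' @param z Numeric vector of ion axial positions at the switch, A.
#' @param lambda_i,lambda_next Restraint centres before/after the switch, A.
#' @param spec A [pull_spec()].
#' @return List with `dW` (total, kcal/mol) and `per_ion` (vector).
#' @export
switch_work <- function(z, lambda_i, lambda_next, spec) {
  per_ion <- 0.5 * spec$k_axial * ((z - lambda_next)^2 - (z - lambda_i)^2)
  list(dW = sum(per_ion), per_ion = per_ion)
}

#' Run a step-wise pulling protocol on a landscape
#'
#' For each replica: relax for tau at each lambda, record frames, compute
#' the switch work at the end-of-relaxation configuration, and seed the next
#' step with that configuration. Returns the trajectory table and the work
#' ledger consumed by the Jarzynski stage.
#'
#' @param landscape A [landscape_spec()].
#' @param spec A [pull_spec()].
#' @param config A [sim_config()] (its own seed is ignored; streams derive
#'   from `spec$seed`).
#' @param species Species tags for the pulled ions (recycled).
#' @param keep_frames If FALSE, drop the trajectory table (ledger only) to
#'   save memory on large replica sets.
#' @return An object of class `pull_run`: list with `trajectory` (tibble:
#'   replica, step, lambda, time, ion, species, x, y, z), `ledger` (tibble:
#'   replica, step, lambda, dW, W_cum, dW_ion<j>), `schedule`, `spec`,
#'   `direction` ("inward" if lambda increases, else "outward").
#' @export
run_pulling <- function(landscape, spec, config, species = "ion",
                        keep_frames = TRUE) {
  stopifnot(inherits(landscape, "landscape_spec"), inherits(spec, "pull_spec"),
            inherits(config, "sim_config"))
  sched <- build_schedule(spec)
  place <- as_position_matrix(spec$initial_placement)
  n_ion <- nrow(place)
  species <- rep_len(species, n_ion)
  bias_k <- cbind(rep(spec$k_lateral, n_ion), rep(spec$k_lateral, n_ion),
                  rep(spec$k_axial, n_ion))
  check_stability(landscape_stiffness(landscape) + max(bias_k), config)
  n_relax <- max(1L, round(spec$tau / config$timestep))
  stride <- max(1L, round(spec$recording_interval / config$timestep))

  one_replica <- function(rep_id) {
    pos <- place
    frames <- vector("list", spec$n_steps)
    work <- matrix(0, nrow = spec$n_steps - 1, ncol = n_ion)
    for (i in seq_len(spec$n_steps)) {
      bias_c <- cbind(rep(spec$xy_center[1], n_ion),
                      rep(spec$xy_center[2], n_ion), rep(sched[i], n_ion))
      run <- run_brownian(landscape, config, pos, species,
                          n_steps = n_relax,
                          seed = seed_stream(spec$seed, (rep_id - 1) *
                                               spec$n_steps + i),
                          bias_k = bias_k, bias_center = bias_c,
                          record_stride = stride,
                          t0 = (i - 1) * spec$tau)
      pos <- run$final
      if (keep_frames && !is.null(run$frames)) {
        frames[[i]] <- dplyr::mutate(run$frames, replica = rep_id, step = i,
                                     lambda = sched[i], .before = 1)
      }
      if (i < spec$n_steps) {
        work[i, ] <- switch_work(pos[, 3], sched[i], sched[i + 1], spec)$per_ion
      }
    }
    ledger <- tibble::tibble(replica = rep_id,
                             step = seq_len(spec$n_steps - 1),
                             lambda = sched[-1],
                             dW = rowSums(work))
    ledger$W_cum <- cumsum(ledger$dW)
    for (j in seq_len(n_ion)) ledger[[paste0("dW_ion", j)]] <- work[, j]
    list(frames = if (keep_frames) dplyr::bind_rows(frames) else NULL,
         ledger = ledger)
  }

  reps <- lapply(seq_len(spec$n_replicas), one_replica)
  structure(list(
    trajectory = if (keep_frames)
      dplyr::bind_rows(lapply(reps, `[[`, "frames")) else NULL,
    ledger = dplyr::bind_rows(lapply(reps, `[[`, "ledger")),
    schedule = sched, spec = spec,
    species = species,
    direction = if (spec$lambda_increment >= 0) "inward" else "outward"),
    class = "pull_run")
}

#' @export
print.pull_run <- function(x, ...) {
  cat("<pull_run> ", x$direction, " pulling, ", x$spec$n_replicas,
      " replicas x ", x$spec$n_steps, " steps (lambda ",
      x$schedule[1], " -> ", x$schedule[length(x$schedule)], " A)\n", sep = "")
  invisible(x)
}
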