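#' Per-ion axial position histograms
#'
#' Histograms the axial coordinate of every ion over all frames of a
#' trajectory; peaks mark stable binding positions in the filter, and their
#' separation distinguishes discrete single-file sites from overlapping
#' ones.
#'
#' @param trajectory Trajectory tibble with at least columns `ion`,
#'   `species`, `z`.
#' @param bin_width Bin width, A (> 0).
#' @return A tibble with columns `ion`, `species`, `z` (bin mid), `count`.
#' @export
axial_histograms <- function(trajectory, bin_width = 0.5) {
  if (bin_width <= 0) stop("`bin_width` must be > 0")
  if (is.null(trajectory) || nrow(trajectory) == 0) stop("empty trajectory")
  lo <- floor(min(trajectory$z) / bin_width) * bin_width
  dplyr::reframe(
    dplyr::group_by(trajectory, .data$ion, .data$species),
    {
      idx <- floor((z - lo) / bin_width) + 1
      cnt <- tabulate(idx)
      data.frame(z = lo + (seq_along(cnt) - 0.5) * bin_width, count = cnt)
    })
}

#' Two-ion axial density map
#'
#' Counts frames on a (z1, z2) grid for a designated ordered pair of ions:
#' the pair-coordinate density whose diagonal concentration reveals a
#' blocking ("pass-by") state.
#'
#' @param trajectory Trajectory tibble (columns `time`, `ion`, `z`; `replica`
#'   and `step` respected if present).
#' @param ions Length-2 integer: which two ion indices form the pair.
#' @param z_range Grid range on both axes, A.
#' @param bin Bin width, A.
#' @param symmetrize If TRUE, counts are symmetrised under ion relabelling
#'   (each frame contributes to (z1, z2) and (z2, z1)).
#' @return A `pair_density` object: list with `counts` matrix, `axes`,
#'   `frames` (frames that fell inside the grid), `total_frames`.
#' @export
pair_density <- function(trajectory, ions = c(1, 2), z_range = c(-17.5, -4),
                         bin = 0.5, symmetrize = FALSE) {
  stopifnot(length(ions) == 2)
  if (length(unique(trajectory$ion)) < 2) stop("need at least 2 ions")
  key <- c("time", intersect(c("replica", "step"), names(trajectory)))
  a <- trajectory[trajectory$ion == ions[1], c(key, "z")]
  b <- trajectory[trajectory$ion == ions[2], c(key, "z")]
  m <- dplyr::inner_join(a, b, by = key, suffix = c("1", "2"))
  mids <- seq(z_range[1] + bin / 2, z_range[2] - bin / 2, by = bin)
  ax <- list(min = z_range[1], max = z_range[2], bin = bin, mids = mids)
  z1 <- m$z1; z2 <- m$z2
  if (symmetrize) { z1 <- c(m$z1, m$z2); z2 <- c(m$z2, m$z1) }
  counts <- bin_histogram2(z1, z2, ax, ax)
  structure(list(counts = counts, axes = list(ax, ax),
                 frames = sum(counts), total_frames = nrow(m),
                 symmetrized = symmetrize),
            class = "pair_density")
}

#' @export
print.pair_density <- function(x, ...) {
  cat("<pair_density> ", nrow(x$counts), " x ", ncol(x$counts), " bins, ",
      x$frames, "/", x$total_frames, " frames in range",
      if (x$symmetrized) " (symmetrized)", "\n", sep = "")
  invisible(x)
}

#' Detect a blocking area in a pair-density map
#'
#' Looks for a contiguous stretch of the same-z diagonal band
#' (|z1 - z2| <= `delta_diag`) that concentrates at least `theta_occ` of all
#' frames: the signature of two ions wedged side by side. Diagonal positions
#' with negligible occupancy (below `floor_frac` of frames) break
#' contiguity, so the reported extent is that of the occupied diagonal
#' stretch, not of the whole band.
#'
#' @param map A [pair_density()] result.
#' @param delta_diag Same-z band half-width, A (default 1, matching
#'   [classify_pair_configuration()]).
#' @param theta_occ Minimum pooled occupancy fraction for detection.
#' @param floor_frac Per-diagonal-bin occupancy below which a bin counts as
#'   empty.
#' @param trajectory Optional trajectory (same pair of ions) used to compute
#'   the mean 3D inter-ion distance inside the detected region; without it
#'   the mean |z1 - z2| over in-region bins is reported.
#' @param ions Ion pair indices when `trajectory` is given.
#' @return A `block_report`: list with `detected`, `z_lo`, `z_hi` (centres
#'   of the first and last occupied diagonal positions), `extent`
#'   (z_hi - z_lo, A along the diagonal coordinate), `occupancy`,
#'   `mean_distance`. An undetected block is a valid result, not an error.
#' @export
detect_block <- function(map, delta_diag = 1.0, theta_occ = 0.2,
                         floor_frac = 0.005, trajectory = NULL,
                         ions = c(1, 2)) {
  stopifnot(inherits(map, "pair_density"))
  if (map$frames == 0) stop("pair-density map is empty")
  ax <- map$axes[[1]]
  nb <- length(ax$mids)
  z1g <- matrix(ax$mids, nb, nb)
  z2g <- matrix(map$axes[[2]]$mids, nb, nb, byrow = TRUE)
  band <- abs(z1g - z2g) <= delta_diag
  # diagonal coordinate s = (z1 + z2)/2, discretised on the grid pitch
  s_idx <- floor((z1g + z2g) / 2 / ax$bin + 0.5)
  s_vals <- sort(unique(as.vector(s_idx[band])))
  mass <- vapply(s_vals, function(s)
    sum(map$counts[band & s_idx == s]), numeric(1))
  occ <- mass / map$total_frames
  occupied <- occ >= floor_frac
  runs <- split(seq_along(s_vals), cumsum(!occupied)[seq_along(s_vals)])
  runs <- lapply(runs, function(r) r[occupied[r]])
  runs <- runs[vapply(runs, length, integer(1)) > 0]
  best <- NULL; best_occ <- 0
  for (r in runs) {
    pooled <- sum(occ[r])
    if (pooled >= theta_occ && pooled > best_occ) {
      best <- r; best_occ <- pooled
    }
  }
  if (is.null(best)) {
    rep <- list(detected = FALSE, z_lo = NA_real_, z_hi = NA_real_,
                extent = 0, occupancy = max(c(0, vapply(runs, function(r)
                  sum(occ[r]), numeric(1)))),
                mean_distance = NA_real_,
                delta_diag = delta_diag, theta_occ = theta_occ)
    return(structure(rep, class = "block_report"))
  }
  # endpoints are the centres of the first/last occupied diagonal positions,
  # so grid quantisation cannot inflate the extent beyond the true span
  z_lo <- s_vals[best[1]] * ax$bin
  z_hi <- s_vals[best[length(best)]] * ax$bin
  in_region <- band & s_idx >= s_vals[best[1]] & s_idx <= s_vals[best[length(best)]]
  mean_dz <- sum(abs(z1g - z2g)[in_region] * map$counts[in_region]) /
    sum(map$counts[in_region])
  mean_dist <- mean_dz
  if (!is.null(trajectory)) {
    key <- c("time", intersect(c("replica", "step"), names(trajectory)))
    a <- trajectory[trajectory$ion == ions[1], c(key, "x", "y", "z")]
    b <- trajectory[trajectory$ion == ions[2], c(key, "x", "y", "z")]
    m <- dplyr::inner_join(a, b, by = key, suffix = c("1", "2"))
    s <- (m$z1 + m$z2) / 2
    sel <- abs(m$z1 - m$z2) <= delta_diag & s >= z_lo & s <= z_hi
    if (any(sel))
      mean_dist <- mean(sqrt((m$x1 - m$x2)^2 + (m$y1 - m$y2)^2 +
                               (m$z1 - m$z2)^2)[sel])
  }
  structure(list(detected = TRUE, z_lo = z_lo, z_hi = z_hi,
                 extent = z_hi - z_lo, occupancy = best_occ,
                 mean_distance = mean_dist,
                 delta_diag = delta_diag, theta_occ = theta_occ),
            class = "block_report")
}

#' @export
print.block_report <- function(x, ...) {
  if (x$detected) {
    cat(sprintf(paste0("<block_report> DETECTED: diagonal stretch [%.2f, ",
                       "%.2f] A (extent %.2f A), occupancy %.2f\n"),
                x$z_lo, x$z_hi, x$extent, x$occupancy))
  } else {
    cat(sprintf("<block_report> not detected (best band occupancy %.3f < %.2f)\n",
                x$occupancy, x$theta_occ))
  }
  invisible(x)
}

#' Inter-ion separation and shared-solvent count per pulling step
#'
#' For each frame, computes the pair distance r12 and counts solvent points
#' lying within r12 of *both* ions (the lens-shaped overlap of the two
#' spheres of radius r12 centred on the ions); a falling shared count with
#' rising separation is the dehydration signature of the block. Averages are
#' taken per pulling step over the final fraction of each relaxation window.
#'
#' @param trajectory Pulling trajectory (columns `replica`, `step`, `time`,
#'   `ion`, `x`, `y`, `z`).
#' @param solvent Either a tibble of solvent points with a `time` column
#'   matching trajectory frame times (plus `x`, `y`, `z`), or a function
#'   `function(time)` returning the point set of that frame.
#' @param ions Length-2 ion indices forming the pair.
#' @param window_fraction Final fraction of each step's relaxation window
#'   used for the averages (default 2.5/3, i.e. all but the first sixth).
#' @return A tibble with columns `step`, `lambda` (if present), `mean_r12`,
#'   `mean_shared`, `n_frames`.
#' @export
separation_and_solvent <- function(trajectory, solvent, ions = c(1, 2),
                                   window_fraction = 2.5 / 3) {
  key <- c("time", intersect(c("replica", "step", "lambda"),
                             names(trajectory)))
  a <- trajectory[trajectory$ion == ions[1], c(key, "x", "y", "z")]
  b <- trajectory[trajectory$ion == ions[2], c(key, "x", "y", "z")]
  m <- dplyr::inner_join(a, b, by = key, suffix = c("1", "2"))
  if (nrow(m) == 0) stop("no aligned frames for the requested ion pair")
  m$r12 <- sqrt((m$x1 - m$x2)^2 + (m$y1 - m$y2)^2 + (m$z1 - m$z2)^2)
  solvent_for <- if (is.function(solvent)) {
    solvent
  } else {
    if (!("time" %in% names(solvent)))
      stop("`solvent` table needs a `time` column aligned with the trajectory")
    function(t) solvent[abs(solvent$time - t) < 1e-9, ]
  }
  m$shared <- vapply(seq_len(nrow(m)), function(i) {
    pts <- solvent_for(m$time[i])
    if (is.null(pts) || nrow(pts) == 0) return(0L)
    d1 <- sqrt((pts$x - m$x1[i])^2 + (pts$y - m$y1[i])^2 + (pts$z - m$z1[i])^2)
    d2 <- sqrt((pts$x - m$x2[i])^2 + (pts$y - m$y2[i])^2 + (pts$z - m$z2[i])^2)
    sum(d1 <= m$r12[i] & d2 <= m$r12[i])
  }, integer(1))
  if (!is.function(solvent)) {
    miss <- !(m$time %in% solvent$time)
    if (any(miss)) stop("solvent point sets are not time-aligned with the ",
                        "trajectory (first missing time: ",
                        format(m$time[miss][1]), ")")
  }
  if (!("step" %in% names(m))) m$step <- 1L
  has_lambda <- "lambda" %in% names(m)
  dplyr::summarise(
    dplyr::group_by(m, .data$step),
    lambda = if (has_lambda) .data$lambda[1] else NA_real_,
    mean_r12 = {
      keep <- .data$time - min(.data$time) >=
        (1 - window_fraction) * (max(.data$time) - min(.data$time)) - 1e-9
      mean(.data$r12[keep])
    },
    mean_shared = {
      keep <- .data$time - min(.data$time) >=
        (1 - window_fraction) * (max(.data$time) - min(.data$time)) - 1e-9
      mean(.data$shared[keep])
    },
    n_frames = dplyr::n(), .groups = "drop")
}

#' Compare inward and outward free-energy profiles
#'
#' Quantifies directional (functional) asymmetry from two matched pulling
#' profiles: the maximum cumulative work each direction requires over the
#' filter span, their difference, and the block-escape work of each profile
#' (the rise from the profile minimum inside the block region to the highest
#' point before the next local minimum -- the energy an external force must
#' supply to break a block).
#'
#' @param inward,outward Matched `pull_run` objects (preferred) or
#'   `free_energy_profile`s from matched landscapes and protocols.
#' @param filter_span Lambda range of the filter, A.
#' @param block_region Lambda range where the block state lives, A.
#' @param n_boot When `pull_run`s are supplied, number of replica-bootstrap
#'   resamples used for the uncertainty of the escape difference (the
#'   cumulative profile points are strongly correlated, so resampling whole
#'   replicas is the honest error model). With profile-only input the
#'   uncertainty falls back to quadrature of the endpoint errors, which
#'   overstates it.
#' @param boot_seed Seed for the bootstrap resampling.
#' @param temperature Temperature for re-estimating profiles from ledgers, K.
#' @return A list of class `asymmetry_report`: `max_work_inward`,
#'   `max_work_outward`, `difference`, `escape_inward`, `escape_outward`,
#'   `escape_difference`, `joint_se`.
#' @export
asymmetry_summary <- function(inward, outward, filter_span = c(-15, -5),
                              block_region = c(-15, -10), n_boot = 200,
                              boot_seed = 1L, temperature = 300) {
  runs <- NULL
  if (inherits(inward, "pull_run") && inherits(outward, "pull_run")) {
    runs <- list(inward = inward, outward = outward)
    inward <- jarzynski_profile(inward, temperature, per_ion = FALSE)
    outward <- jarzynski_profile(outward, temperature, per_ion = FALSE)
  }
  for (p in list(inward, outward)) {
    if (!all(c("lambda", "dF") %in% names(p)))
      stop("profiles must have `lambda` and `dF` columns")
  }
  if (max(inward$lambda) < min(outward$lambda) ||
      max(outward$lambda) < min(inward$lambda))
    stop("profiles cover non-overlapping lambda ranges")
  span_max <- function(p) {
    sel <- p$lambda >= filter_span[1] & p$lambda <= filter_span[2]
    if (!any(sel)) stop("profile does not cover the filter span")
    max(p$dF[sel])
  }
  escape <- function(p) {
    sel <- which(p$lambda >= block_region[1] & p$lambda <= block_region[2])
    if (length(sel) == 0) return(list(w = NA_real_, se = NA_real_))
    i0 <- sel[which.min(p$dF[sel])]
    # escape is a filter phenomenon: the search stops where the restraint
    # centre leaves the filter span, so bulk extraction work far outside the
    # filter is not attributed to the block
    in_span <- p$lambda >= filter_span[1] & p$lambda <= filter_span[2]
    n <- max(which(in_span))
    if (i0 >= n) return(list(w = 0, se = 0))
    # walk forward in protocol order to the first local minimum past i0
    stop_at <- n
    for (j in seq(i0 + 1, max(i0 + 1, n - 1))) {
      if (j > i0 + 1 && p$dF[j] <= p$dF[j - 1] && p$dF[j] <= p$dF[j + 1]) {
        stop_at <- j
        break
      }
    }
    w <- max(p$dF[(i0 + 1):stop_at]) - p$dF[i0]
    imax <- i0 + which.max(p$dF[(i0 + 1):stop_at])
    se <- if ("dF_se" %in% names(p))
      sqrt(p$dF_se[i0]^2 + p$dF_se[imax]^2) else NA_real_
    list(w = w, se = se)
  }
  ei <- escape(inward); eo <- escape(outward)
  joint_se <- sqrt((if (is.na(ei$se)) 0 else ei$se)^2 +
                     (if (is.na(eo$se)) 0 else eo$se)^2)
  if (!is.null(runs) && n_boot > 0) {
    boot_escape <- function(run, idx) {
      # resampled replicas keep multiplicity via renumbered copies
      led <- dplyr::bind_rows(lapply(seq_along(idx), function(i) {
        d <- run$ledger[run$ledger$replica == idx[i], ]
        d$replica <- i
        d
      }))
      boot_run <- run
      boot_run$ledger <- led
      boot_run$trajectory <- NULL
      p <- jarzynski_profile(boot_run, temperature, per_ion = FALSE)
      escape(p)$w
    }
    reps_i <- unique(runs$inward$ledger$replica)
    reps_o <- unique(runs$outward$ledger$replica)
    diffs <- withr::with_seed(boot_seed, {
      vapply(seq_len(n_boot), function(b) {
        bi <- boot_escape(runs$inward, sample(reps_i, replace = TRUE))
        bo <- boot_escape(runs$outward, sample(reps_o, replace = TRUE))
        bi - bo
      }, numeric(1))
    })
    joint_se <- stats::sd(diffs)
  }
  structure(list(max_work_inward = span_max(inward),
                 max_work_outward = span_max(outward),
                 difference = span_max(inward) - span_max(outward),
                 escape_inward = ei$w, escape_outward = eo$w,
                 escape_difference = ei$w - eo$w,
                 joint_se = joint_se),
            class = "asymmetry_report")
}

#' @export
print.asymmetry_report <- function(x, ...) {
  cat("<asymmetry_report>\n")
  cat(sprintf("  max work over filter span: inward %.2f, outward %.2f ",
              x$max_work_inward, x$max_work_outward))
  cat(sprintf("(difference %.2f kcal/mol)\n", x$difference))
  cat(sprintf("  block-escape work: inward %.2f, outward %.2f kcal/mol ",
              x$escape_inward, x$escape_outward))
  cat(sprintf("(difference %.2f +/- %.2f)\n", x$escape_difference,
              x$joint_se))
  invisible(x)
}
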