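#' Define a model free-energy landscape for ions in a channel
#'
#' The landscape is the ground truth that the Brownian simulator samples and
#' that the pulling / umbrella-sampling stages are validated against. It is a
#' desk-scale stand-in for the environment a selectivity filter presents to
#' permeating ions, with four energy terms:
#' \itemize{
#'   \item axial Gaussian features \eqn{U_0(z) = \sum_j d_j e^{-(z-c_j)^2/2w_j^2}}
#'     (negative depth = well, positive = barrier);
#'   \item harmonic lateral confinement \eqn{0.5\,k_l(x^2+y^2)} toward the
#'     pore axis;
#'   \item screened ion-ion repulsion \eqn{V(r) = A e^{-r/\ell}/r}, clamped
#'     to its r = 1 A value below 1 A (the soft core prevents numerical
#'     blow-up at contact; in the real channel, shared waters provide the
#'     screening);
#'   \item pair "coordination" features active only when two ions sit near
#'     the same z: \eqn{d\, e^{-(\bar z - z_c)^2/2w^2} e^{-\Delta z^2/2t^2}}
#'     with \eqn{\bar z} the pair mean z and \eqn{\Delta z} the separation.
#'     These create the side-by-side ("pass-by") minima that make a K-like
#'     filter blockable.
#' }
#'
#' The coordinate convention has z increasing in the inward direction, with
#' the filter spanning z = -15 A (entrance) to -5 A (cavity side).
#'
#' @param species_label Text tag, e.g. "K-like" or "Na-like".
#' @param axial_features Data frame with columns `center` (A), `depth`
#'   (kcal/mol) and `width` (A), one row per Gaussian term of U0(z).
#' @param lateral_k Lateral confinement constant, kcal/mol/A^2 (>= 0).
#' @param pair_amplitude Screened-repulsion amplitude A, kcal*A/mol (>= 0).
#' @param pair_screening Screening length l, A (> 0).
#' @param coordination_features Data frame with columns `z_center`, `depth`,
#'   `width`, `same_z_tolerance`, or NULL for none.
#' @return An object of class `landscape_spec`.
#' @seealso [preset_landscape()] for the shipped K-like and Na-like surfaces,
#'   [evaluate_landscape()], [pair_surface()].
#' @export
landscape_spec <- function(species_label = "custom",
                           axial_features = data.frame(center = numeric(),
                                                       depth = numeric(),
                                                       width = numeric()),
                           lateral_k = 0.5,
                           pair_amplitude = 0,
                           pair_screening = 3,
                           coordination_features = NULL) {
  axial_features <- as.data.frame(axial_features)
  stopifnot(all(c("center", "depth", "width") %in% names(axial_features)))
  if (nrow(axial_features) > 0 && any(axial_features$width <= 0))
    stop("all axial feature widths must be > 0")
  if (pair_screening <= 0) stop("`pair_screening` must be > 0")
  if (pair_amplitude < 0) stop("`pair_amplitude` must be >= 0")
  if (lateral_k < 0) stop("`lateral_k` must be >= 0")
  if (is.null(coordination_features)) {
    coordination_features <- data.frame(z_center = numeric(), depth = numeric(),
                                        width = numeric(),
                                        same_z_tolerance = numeric())
  }
  coordination_features <- as.data.frame(coordination_features)
  stopifnot(all(c("z_center", "depth", "width", "same_z_tolerance") %in%
                  names(coordination_features)))
  if (nrow(coordination_features) > 0 &&
      any(coordination_features$width <= 0 |
            coordination_features$same_z_tolerance <= 0))
    stop("coordination widths and tolerances must be > 0")
  structure(list(species_label = species_label,
                 axial_features = axial_features,
                 lateral_k = lateral_k,
                 pair_amplitude = pair_amplitude,
                 pair_screening = pair_screening,
                 coordination_features = coordination_features),
            class = "landscape_spec")
}

#' @export
print.landscape_spec <- function(x, ...) {
  cat("<landscape_spec> ", x$species_label, "\n", sep = "")
  cat("  axial features: ", nrow(x$axial_features),
      "; coordination features: ", nrow(x$coordination_features), "\n", sep = "")
  cat("  lateral_k = ", x$lateral_k, " kcal/mol/A^2; pair A = ",
      x$pair_amplitude, " kcal*A/mol, l = ", x$pair_screening, " A\n", sep = "")
  invisible(x)
}

# flat parameter list handed to the C++ kernel
ls_params <- function(spec) {
  list(axial_center = as.numeric(spec$axial_features$center),
       axial_depth = as.numeric(spec$axial_features$depth),
       axial_width = as.numeric(spec$axial_features$width),
       lateral_k = as.numeric(spec$lateral_k),
       pair_amplitude = as.numeric(spec$pair_amplitude),
       pair_screening = as.numeric(spec$pair_screening),
       coord_center = as.numeric(spec$coordination_features$z_center),
       coord_depth = as.numeric(spec$coordination_features$depth),
       coord_width = as.numeric(spec$coordination_features$width),
       coord_tol = as.numeric(spec$coordination_features$same_z_tolerance))
}

# upper bound on local stiffness (kcal/mol/A^2), used by the stability check:
# the max curvature of a Gaussian d*exp(-u^2/2w^2) is |d|/w^2
landscape_stiffness <- function(spec) {
  k <- spec$lateral_k
  if (nrow(spec$axial_features) > 0)
    k <- max(k, abs(spec$axial_features$depth) / spec$axial_features$width^2)
  if (nrow(spec$coordination_features) > 0)
    k <- max(k, abs(spec$coordination_features$depth) *
               (1 / spec$coordination_features$width^2 +
                  2 / spec$coordination_features$same_z_tolerance^2))
  k
}

#' Shipped landscape presets
#'
#' Two calibrated surfaces whose two-ion topology mirrors the qualitative
#' difference between a Na-selective and a K-blockable filter:
#' \describe{
#'   \item{"Na-like"}{Three axial wells about 3 A apart inside the filter and
#'     no pair-coordination terms. On the two-ion surface the diagonal
#'     (same-z, "pass-by") line is a repulsive ridge, so permeation proceeds
#'     only through off-diagonal "knock-on" channels.}
#'   \item{"K-like"}{Weak axial wells plus an entrance barrier and two
#'     same-z coordination wells: the global "pass-by" minimum X near
#'     z = -8 and the shallower, narrower local minimum Y near the filter
#'     entrance at z = -13.5, separated by a same-z ridge in the middle of
#'     the filter. A pair entering from the extracellular side funnels into
#'     Y and is held there by an inward force (escaping costs the pair
#'     coordination energy), whereas a pair arriving single file from the
#'     cavity passes the ridge region without pairing up. Escape barriers
#'     out of X toward the knock-on channels are a few k_B T, so X alone
#'     does not block.}
#' }
#'
#' @param species "K-like" or "Na-like".
#' @return A [landscape_spec()].
#' @export
#' @examples
#' preset_landscape("K-like")
preset_landscape <- function(species = c("K-like", "Na-like")) {
  species <- match.arg(species)
  if (species == "Na-like") {
    landscape_spec(
      species_label = "Na-like",
      axial_features = data.frame(
        center = c(-16.0, -13.0, -10.0, -7.0),
        depth  = c( 1.5,  -2.5,  -3.5,  -2.5),
        width  = c( 0.8,   1.2,   1.2,   1.2)),
      lateral_k = 0.5,
      pair_amplitude = 10,
      pair_screening = 3)
  } else {
    landscape_spec(
      species_label = "K-like",
      axial_features = data.frame(
        center = c(-15.5, -13.5, -10.0, -7.0, -4.8),
        depth  = c( 1.0,  -0.5,  -3.8,  -1.0,  1.5),
        width  = c( 0.8,   0.7,   0.7,   0.7,  0.6)),
      lateral_k = 0.5,
      pair_amplitude = 8,
      pair_screening = 3,
      coordination_features = data.frame(
        z_center         = c(-13.5, -11.75, -8.75, -5.0),
        depth            = c( -7.4, -10.8,   6.0,   5.0),
        width            = c(  0.7,   0.5,   1.5,   1.2),
        same_z_tolerance = c(  1.0,   0.5,   1.0,   1.2)))
  }
}

#' Evaluate a landscape at one ion configuration
#'
#' Returns the total energy, its term-wise components, and the analytic
#' per-ion force (negative gradient).
#'
#' @param spec A [landscape_spec()].
#' @param positions Data frame or matrix with columns x, y, z (A), one row
#'   per ion (1-3 ions).
#' @return A list with `energy` (kcal/mol), `force` (n x 3 matrix,
#'   kcal/mol/A) and `components` (named vector: axial, lateral, pair,
#'   coordination).
#' @export
#' @examples
#' ls <- preset_landscape("Na-like")
#' evaluate_landscape(ls, data.frame(x = 0, y = 0, z = -10))
evaluate_landscape <- function(spec, positions) {
  stopifnot(inherits(spec, "landscape_spec"))
  pos <- as_position_matrix(positions)
  if (nrow(pos) < 1 || nrow(pos) > 3)
    stop("unsupported configuration: the simulator handles 1-3 ions, got ",
         nrow(pos))
  out <- .landscape_eval_cpp(pos, ls_params(spec))
  colnames(out$force) <- c("x", "y", "z")
  out
}

as_position_matrix <- function(positions) {
  if (is.data.frame(positions)) {
    stopifnot(all(c("x", "y", "z") %in% names(positions)))
    pos <- as.matrix(positions[, c("x", "y", "z")])
  } else {
    pos <- as.matrix(positions)
    if (ncol(pos) != 3) stop("`positions` must have 3 columns (x, y, z)")
  }
  storage.mode(pos) <- "double"
  if (any(!is.finite(pos))) stop("non-finite ion coordinates")
  pos
}

#' Axial potential profile of a landscape
#'
#' Single-ion, on-axis energy U0(z): the analytic reference that
#' [sample_equilibrium()] and the WHAM reconstructions are checked against.
#'
#' @param spec A [landscape_spec()].
#' @param z Numeric vector of axial positions (A).
#' @return A tibble with columns `z` and `energy`.
#' @export
axial_potential <- function(spec, z) {
  stopifnot(inherits(spec, "landscape_spec"))
  e <- vapply(z, function(zi) {
    sum(spec$axial_features$depth *
          exp(-(zi - spec$axial_features$center)^2 /
                (2 * spec$axial_features$width^2)))
  }, numeric(1))
  tibble::tibble(z = z, energy = e)
}

#' Analytic two-ion surface of a landscape
#'
#' Evaluates the on-axis two-ion energy U(z1, z2) on a regular grid. This is
#' the ground-truth analogue of the two-dimensional PMF that umbrella
#' sampling + WHAM reconstructs, and is what the preset topology assertions
#' (same-z minima X and Y for the K-like surface, none for Na-like) are made
#' on.
#'
#' @param spec A [landscape_spec()].
#' @param z_range Length-2 numeric, grid range on both axes (A).
#' @param bin Grid spacing (A).
#' @return A `pmf_grid` object (see [wham_solve()]) with the analytic energy
#'   offset so its minimum is 0.
#' @export
pair_surface <- function(spec, z_range = c(-17.5, -4), bin = 0.5) {
  stopifnot(inherits(spec, "landscape_spec"))
  mids <- seq(z_range[1] + bin / 2, z_range[2] - bin / 2, by = bin)
  p <- ls_params(spec)
  vals <- outer(mids, mids, Vectorize(function(z1, z2) {
    .landscape_eval_cpp(rbind(c(0, 0, z1), c(0, 0, z2)), p)$energy
  }))
  vals <- vals - min(vals)
  new_pmf_grid(values = vals,
               axes = list(list(min = z_range[1], max = z_range[2], bin = bin,
                                mids = mids),
                           list(min = z_range[1], max = z_range[2], bin = bin,
                                mids = mids)),
               temperature = NA_real_, iterations = 0L, residual = 0,
               converged = TRUE,
               source = paste0("analytic:", spec$species_label))
}
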