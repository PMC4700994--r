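#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a PMF grid into a long tibble
#'
#' @param x A `pmf_grid`.
#' @param drop_masked Drop unsampled (NA) bins.
#' @param ... Unused.
#' @return A tibble with `z1` (`z` in 1D), `z2` and `pmf` columns.
#' @export
tidy.pmf_grid <- function(x, drop_masked = TRUE, ...) {
  if (x$dim == 1) {
    out <- tibble::tibble(z = x$axes[[1]]$mids, pmf = x$values)
  } else {
    out <- tibble::tibble(
      z1 = rep(x$axes[[1]]$mids, times = length(x$axes[[2]]$mids)),
      z2 = rep(x$axes[[2]]$mids, each = length(x$axes[[1]]$mids)),
      pmf = as.vector(x$values))
  }
  if (drop_masked) out <- out[!is.na(out$pmf), ]
  out
}

#' One-row summary of a PMF grid
#'
#' @param x A `pmf_grid`.
#' @param ... Unused.
#' @return A tibble with dimensionality, bin counts, sampled fraction,
#'   iteration count, residual and convergence flag.
#' @export
glance.pmf_grid <- function(x, ...) {
  tibble::tibble(dim = x$dim,
                 n_bins = length(x$values),
                 sampled_fraction = mean(!is.na(x$values)),
                 max_pmf = max(x$values, na.rm = TRUE),
                 iterations = x$iterations,
                 residual = x$residual,
                 converged = x$converged)
}

#' Tidy a block report
#'
#' @param x A `block_report`.
#' @param ... Unused.
#' @return One-row tibble with the detection flag and region statistics.
#' @export
tidy.block_report <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Tidy an asymmetry report
#'
#' @param x An `asymmetry_report`.
#' @param ... Unused.
#' @return One-row tibble of the per-direction work maxima, escape works and
#'   their differences.
#' @export
tidy.asymmetry_report <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' One-row summary of a free-energy profile
#'
#' @param x A `free_energy_profile`.
#' @param ... Unused.
#' @return A tibble with the direction, lambda range, final and maximum dF
#'   and its uncertainty.
#' @export
glance.free_energy_profile <- function(x, ...) {
  tibble::tibble(direction = attr(x, "direction"),
                 lambda_start = x$lambda[1],
                 lambda_end = x$lambda[nrow(x)],
                 dF_final = x$dF[nrow(x)],
                 dF_max = max(x$dF),
                 se_final = x$dF_se[nrow(x)])
}

#' Plot a free-energy profile
#'
#' Total dF(lambda) with an uncertainty ribbon, plus per-ion component
#' profiles when present.
#'
#' @param object A `free_energy_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.free_energy_profile <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ion_cols <- grep("^dF_ion", names(df), value = TRUE)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$lambda, y = .data$dF)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$dF - .data$dF_se,
                                      ymax = .data$dF + .data$dF_se),
                         alpha = 0.2) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = expression(lambda ~ "(Å)"),
                  y = expression(Delta * F ~ "(kcal/mol)"),
                  title = paste0("Perturbed free-energy profile (",
                                 attr(object, "direction"), ")"))
  if (length(ion_cols) > 0) {
    long <- tidyr::pivot_longer(df[, c("lambda", ion_cols)],
                                dplyr::all_of(ion_cols),
                                names_to = "ion", values_to = "dF")
    long$ion <- sub("dF_ion", "ion ", long$ion)
    p <- p + ggplot2::geom_line(data = long,
                                ggplot2::aes(colour = .data$ion),
                                linetype = "dashed")
  }
  p
}

#' Plot a PMF grid
#'
#' 1D grids as a line; 2D grids as a filled raster with the same-z diagonal
#' marked.
#'
#' @param object A `pmf_grid`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pmf_grid <- function(object, ...) {
  df <- tidy(object)
  if (object$dim == 1) {
    return(ggplot2::ggplot(df, ggplot2::aes(x = .data$z, y = .data$pmf)) +
             ggplot2::geom_line() +
             ggplot2::labs(x = "z (Å)", y = "PMF (kcal/mol)"))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z1, y = .data$z2,
                                   fill = .data$pmf)) +
    ggplot2::geom_raster() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "white") +
    ggplot2::scale_fill_viridis_c(name = "PMF\n(kcal/mol)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = expression(z[1] ~ "(Å)"),
                  y = expression(z[2] ~ "(Å)"))
}

#' Plot a pair-density map
#'
#' @param object A `pair_density`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pair_density <- function(object, ...) {
  df <- tibble::tibble(
    z1 = rep(object$axes[[1]]$mids, times = length(object$axes[[2]]$mids)),
    z2 = rep(object$axes[[2]]$mids, each = length(object$axes[[1]]$mids)),
    count = as.vector(object$counts))
  ggplot2::ggplot(df[df$count > 0, ],
                  ggplot2::aes(x = .data$z1, y = .data$z2,
                               fill = .data$count)) +
    ggplot2::geom_raster() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::scale_fill_viridis_c(trans = "log10", name = "frames") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = expression(z[1] ~ "(Å)"),
                  y = expression(z[2] ~ "(Å)"))
}
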