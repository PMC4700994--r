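#' Generate umbrella-sampling windows over one or two axial coordinates
#'
#' Tiles the requested range(s) with harmonic bias windows at regular
#' spacing. Neighbouring windows overlap adequately when the bias thermal
#' width sqrt(k_B T / k_umb) is at least half the spacing; a warning is
#' raised otherwise.
#'
#' @param ranges A length-2 numeric range (1D), or a list of two ranges
#'   (2D, one per ion's axial coordinate).
#' @param spacing Window centre spacing, A (> 0).
#' @param k_umb Bias spring constant, kcal/mol/A^2 (applied on each biased
#'   coordinate). Default 10, the conventional stiff umbrella value.
#' @param grid_bin Histogram bin width of the shared analysis grid, A.
#' @param temperature Temperature used for the overlap check, K.
#' @return A tibble of windows (`window`, `center1`, `k1`, and `center2`,
#'   `k2` in 2D) carrying the shared grid specification as attribute
#'   `"grid"`.
#' @export
#' @examples
#' generate_windows(c(-20, -2), spacing = 1) # 19 windows
generate_windows <- function(ranges, spacing, k_umb = 10, grid_bin = 0.5,
                             temperature = 300) {
  if (spacing <= 0) stop("`spacing` must be > 0")
  if (!is.list(ranges)) ranges <- list(ranges)
  stopifnot(length(ranges) %in% c(1, 2))
  for (r in ranges) {
    if (length(r) != 2 || r[2] <= r[1]) stop("empty or invalid range")
  }
  if (sqrt(constants$k_B * temperature / k_umb) < 0.95 * spacing / 2)
    warning(sprintf(paste0("window overlap criterion violated: bias width ",
                           "%.3f A < spacing/2 = %.2f A; histograms may not ",
                           "overlap"),
                    sqrt(constants$k_B * temperature / k_umb), spacing / 2))
  centers <- lapply(ranges, function(r) seq(r[1], r[2], by = spacing))
  grid <- lapply(ranges, function(r) {
    lo <- r[1] - 3 * sqrt(constants$k_B * temperature / k_umb)
    hi <- r[2] + 3 * sqrt(constants$k_B * temperature / k_umb)
    lo <- floor(lo / grid_bin) * grid_bin
    hi <- ceiling(hi / grid_bin) * grid_bin
    list(min = lo, max = hi, bin = grid_bin,
         mids = seq(lo + grid_bin / 2, hi - grid_bin / 2, by = grid_bin))
  })
  if (length(centers) == 1) {
    w <- tibble::tibble(window = seq_along(centers[[1]]),
                        center1 = centers[[1]], k1 = k_umb)
  } else {
    cc <- expand.grid(center1 = centers[[1]], center2 = centers[[2]])
    w <- tibble::tibble(window = seq_len(nrow(cc)),
                        center1 = cc$center1, k1 = k_umb,
                        center2 = cc$center2, k2 = k_umb)
  }
  attr(w, "grid") <- grid
  w
}

window_dim <- function(windows) if ("center2" %in% names(windows)) 2L else 1L

#' Run biased sampling for umbrella windows
#'
#' For each window, runs Brownian dynamics with the harmonic bias added to
#' the landscape forces (one ion biased on z in 1D; two ions, each biased on
#' its own z, in 2D), discards a burn-in fraction, and histograms the biased
#' coordinate(s) on the shared grid.
#'
#' @param landscape A [landscape_spec()].
#' @param windows Window tibble from [generate_windows()].
#' @param config A [sim_config()]; per-window seeds derive from its seed.
#' @param n_frames Recorded frames kept per window (after burn-in).
#' @param burn_in Fraction of frames discarded (default 0.1).
#' @param species Species tag(s) for the sampled ion(s).
#' @return The window tibble with list-column `counts` (histogram arrays on
#'   the shared grid) and column `N` (frames per window).
#' @export
harvest_windows <- function(landscape, windows, config, n_frames,
                            burn_in = 0.1, species = "ion") {
  grid <- attr(windows, "grid")
  if (is.null(grid)) stop("`windows` must carry a shared grid; use ",
                          "generate_windows()")
  d <- window_dim(windows)
  n_total <- ceiling(n_frames / (1 - burn_in))
  stride <- max(1L, round(config$recording_interval / config$timestep))
  species <- rep_len(species, d)
  res <- lapply(seq_len(nrow(windows)), function(i) {
    if (d == 1) {
      pos <- cbind(0, 0, windows$center1[i])
      bias_k <- cbind(0, 0, windows$k1[i])
      bias_c <- cbind(0, 0, windows$center1[i])
    } else {
      pos <- rbind(c(0, 0, windows$center1[i]), c(0, 0, windows$center2[i]))
      bias_k <- rbind(c(0, 0, windows$k1[i]), c(0, 0, windows$k2[i]))
      bias_c <- pos
    }
    run <- run_brownian(landscape, config, pos, species,
                        n_steps = n_total * stride,
                        seed = seed_stream(config$seed, windows$window[i]),
                        bias_k = bias_k, bias_center = bias_c,
                        record_stride = stride)
    f <- run$frames
    keep <- f$time > (n_total - n_frames) * config$recording_interval * 0.999
    f <- f[keep, ]
    if (d == 1) {
      bin_histogram(f$z[f$ion == 1], grid[[1]])
    } else {
      bin_histogram2(f$z[f$ion == 1], f$z[f$ion == 2], grid[[1]], grid[[2]])
    }
  })
  windows$counts <- res
  windows$N <- vapply(res, sum, numeric(1))
  if (any(windows$N == 0)) stop("window with zero accepted frames")
  windows
}

bin_histogram <- function(x, axis) {
  idx <- floor((x - axis$min) / axis$bin) + 1
  idx <- idx[idx >= 1 & idx <= length(axis$mids)]
  tabulate(idx, nbins = length(axis$mids))
}

bin_histogram2 <- function(x, y, ax1, ax2) {
  i <- floor((x - ax1$min) / ax1$bin) + 1
  j <- floor((y - ax2$min) / ax2$bin) + 1
  ok <- i >= 1 & i <= length(ax1$mids) & j >= 1 & j <= length(ax2$mids)
  h <- matrix(0L, length(ax1$mids), length(ax2$mids))
  if (any(ok)) {
    tt <- table(factor(i[ok], levels = seq_along(ax1$mids)),
                factor(j[ok], levels = seq_along(ax2$mids)))
    h <- matrix(as.integer(tt), length(ax1$mids), length(ax2$mids))
  }
  h
}

new_pmf_grid <- function(values, axes, temperature, iterations, residual,
                         converged, source = "wham", f = NULL) {
  structure(list(values = values, axes = axes, dim = length(axes),
                 temperature = temperature, iterations = iterations,
                 residual = residual, converged = converged, source = source,
                 f = f),
            class = "pmf_grid")
}

#' @export
print.pmf_grid <- function(x, ...) {
  cat("<pmf_grid> ", x$dim, "D, ",
      paste(vapply(x$axes, function(a) length(a$mids), integer(1)),
            collapse = " x "),
      " bins (", sum(!is.na(x$values)), " sampled), source: ", x$source,
      "\n", sep = "")
  if (x$source == "wham")
    cat("  ", x$iterations, " iterations, residual ",
        format(x$residual, digits = 3), if (!x$converged) " (NOT converged)",
        "\n", sep = "")
  invisible(x)
}

#' Solve the WHAM equations for a set of umbrella windows
#'
#' Self-consistent reconstruction of the unbiased probability P(xi) from
#' overlapping biased histograms:
#' P(xi) = sum_k h_k(xi) / sum_k N_k exp[(f_k - U_k(xi))/k_B T], with window
#' free energies f_k = -k_B T log sum_xi P(xi) exp(-U_k(xi)/k_B T), iterated
#' until the largest change in any f_k falls below `tol`. The PMF is
#' -k_B T log P, offset so its sampled minimum is 0; bins with zero total
#' counts are masked (NA), never extrapolated.
#'
#' @param windows Harvested window tibble from [harvest_windows()] (columns
#'   `counts`, `N`, centres and spring constants, grid attribute).
#' @param temperature Temperature, K.
#' @param tol Convergence tolerance on the window free energies, kcal/mol.
#' @param max_iter Iteration cap; if reached the result is flagged
#'   non-converged.
#' @return A `pmf_grid` with the PMF values (vector in 1D, matrix in 2D),
#'   axes, iteration count, final residual and convergence flag.
#' @export
wham_solve <- function(windows, temperature = 300, tol = 1e-7,
                       max_iter = 1e5) {
  grid <- attr(windows, "grid")
  if (is.null(grid) || !("counts" %in% names(windows)))
    stop("`windows` must be harvested (counts on a shared grid)")
  if (nrow(windows) < 1) stop("need at least one window")
  d <- window_dim(windows)
  kt <- constants$k_B * temperature
  if (d == 1) {
    mids <- list(grid[[1]]$mids)
    xi <- matrix(mids[[1]], ncol = 1)
  } else {
    xi <- as.matrix(expand.grid(grid[[1]]$mids, grid[[2]]$mids))
  }
  nb <- nrow(xi)
  K <- nrow(windows)
  H <- Reduce(`+`, lapply(windows$counts, as.numeric))
  H <- as.numeric(H)
  N <- windows$N
  U <- matrix(0, K, nb)
  for (k in seq_len(K)) {
    u <- 0.5 * windows$k1[k] * (xi[, 1] - windows$center1[k])^2
    if (d == 2) u <- u + 0.5 * windows$k2[k] * (xi[, 2] - windows$center2[k])^2
    U[k, ] <- u
  }
  B <- exp(-U / kt)
  f <- rep(0, K)
  iter <- 0L
  resid <- Inf
  sampled <- H > 0
  repeat {
    iter <- iter + 1L
    denom <- as.numeric(crossprod(B, N * exp(f / kt)))
    P <- ifelse(sampled, H / denom, 0)
    P <- P / sum(P)
    f_new <- -kt * log(as.numeric(B %*% P))
    f_new <- f_new - f_new[1]
    resid <- max(abs(f_new - f))
    f <- f_new
    if (resid < tol || iter >= max_iter) break
  }
  pmf <- rep(NA_real_, nb)
  pmf[sampled] <- -kt * log(P[sampled])
  pmf <- pmf - min(pmf, na.rm = TRUE)
  vals <- if (d == 1) pmf else matrix(pmf, length(grid[[1]]$mids),
                                      length(grid[[2]]$mids))
  if (iter >= max_iter && resid >= tol)
    warning("WHAM did not converge in ", max_iter, " iterations (residual ",
            format(resid, digits = 3), ")")
  new_pmf_grid(vals, grid, temperature, iter, resid,
               converged = resid < tol, f = f)
}

#' Find free-energy minima of a 2D PMF grid
#'
#' Local minima are unmasked bins lying below all eight neighbours; each is
#' retained only if its depth below the saddle separating it from deeper
#' territory (its topographic prominence, computed by a union-find sweep in
#' order of increasing energy) is at least `min_depth`. The deepest minimum
#' is labelled "global". A minimum is flagged `same_z` when its two
#' coordinates differ by at most `delta` -- the "pass-by" band where the
#' block state lives.
#'
#' @param grid A 2D `pmf_grid`.
#' @param min_depth Minimum prominence, kcal/mol.
#' @param delta Same-z band half-width, A.
#' @param include_edges If FALSE (default), minima on the grid boundary are
#'   dropped: an extremum with an incomplete neighbourhood is usually a
#'   truncation artifact, not a stationary point of the surface.
#' @return A tibble ordered by depth: `z1`, `z2`, `value`, `prominence`,
#'   `label` ("global"/"local"), `same_z`.
#' @export
find_stationary_points <- function(grid, min_depth = 0.5, delta = 1.0,
                                   include_edges = FALSE) {
  stopifnot(inherits(grid, "pmf_grid"))
  if (grid$dim != 2) stop("`grid` must be 2D")
  v <- grid$values
  if (all(is.na(v))) stop("all bins are masked")
  nr <- nrow(v); nc <- ncol(v)
  ord <- order(v, na.last = NA)
  comp <- integer(nr * nc)        # 0 = unprocessed
  comp_min <- integer(0)          # cell index of each component's minimum
  prominence <- rep(NA_real_, nr * nc)
  neighbours <- function(idx) {
    i <- (idx - 1) %% nr + 1; j <- (idx - 1) %/% nr + 1
    ii <- rep(i + c(-1, 0, 1), 3); jj <- rep(j + c(-1, 0, 1), each = 3)
    ok <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc & !(ii == i & jj == j)
    (jj[ok] - 1) * nr + ii[ok]
  }
  find_root <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  parent <- integer(0)
  for (idx in ord) {
    nb <- neighbours(idx)
    nb_comp <- unique(vapply(nb[comp[nb] > 0], function(n) find_root(comp[n]),
                             integer(1)))
    if (length(nb_comp) == 0) {
      parent <- c(parent, length(parent) + 1L)
      comp_min <- c(comp_min, idx)
      comp[idx] <- length(parent)
    } else {
      vals_min <- v[comp_min[nb_comp]]
      surv <- nb_comp[which.min(vals_min)]
      for (cc in nb_comp) {
        if (cc != surv) {
          prominence[comp_min[cc]] <- v[idx] - v[comp_min[cc]]
          parent[cc] <- surv
        }
      }
      comp[idx] <- surv
    }
  }
  roots <- unique(vapply(seq_along(parent), find_root, integer(1)))
  for (r in roots)
    prominence[comp_min[r]] <- max(v, na.rm = TRUE) - v[comp_min[r]]
  # strict 8-neighbour local minima among prominent cells
  cand <- which(!is.na(prominence) & prominence >= min_depth)
  keep <- vapply(cand, function(idx) {
    nb <- neighbours(idx)
    ok <- all(is.na(v[nb]) | v[nb] > v[idx])
    if (!include_edges && length(nb) < 8) ok <- FALSE
    ok
  }, logical(1))
  cand <- cand[keep]
  if (length(cand) == 0) {
    return(tibble::tibble(z1 = numeric(), z2 = numeric(), value = numeric(),
                          prominence = numeric(), label = character(),
                          same_z = logical()))
  }
  i <- (cand - 1) %% nr + 1; j <- (cand - 1) %/% nr + 1
  out <- tibble::tibble(z1 = grid$axes[[1]]$mids[i],
                        z2 = grid$axes[[2]]$mids[j],
                        value = v[cand], prominence = prominence[cand])
  out <- out[order(out$value), ]
  out$label <- c("global", rep("local", nrow(out) - 1))
  out$same_z <- abs(out$z1 - out$z2) <= delta
  out
}

#' Bottleneck-optimal path between two points of a PMF grid
#'
#' Returns the 8-connected path minimising the maximum energy encountered
#' (the minimax path), the natural notion of a permeation pathway on a
#' free-energy grid: its barrier is the lowest saddle the pair of ions must
#' cross. Ties in the bottleneck are broken by path length, then by a fixed
#' node order, so results are deterministic.
#'
#' @param grid A 2D `pmf_grid`.
#' @param start,end Length-2 coordinates (z1, z2) in A; snapped to the
#'   nearest unmasked bin.
#' @param delta Same-z band half-width used for the path label, A.
#' @return A `path_result`: tibble of path nodes (`z1`, `z2`, `energy`) with
#'   attributes `barrier` (max energy minus start energy) and `label`
#'   ("pathway-I-like knock-on" if the path never enters the same-z band,
#'   "pathway-II-like" if it crosses the diagonal through the band, else
#'   "mixed").
#' @export
minimum_energy_path <- function(grid, start, end, delta = 1.0) {
  stopifnot(inherits(grid, "pmf_grid"))
  if (grid$dim != 2) stop("`grid` must be 2D")
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v)
  snap <- function(pt) {
    i <- which.min(abs(grid$axes[[1]]$mids - pt[1]))
    j <- which.min(abs(grid$axes[[2]]$mids - pt[2]))
    idx <- (j - 1) * nr + i
    if (is.na(v[idx])) stop("start/end bin is masked (unsampled)")
    idx
  }
  s <- snap(start); e <- snap(end)
  # Dijkstra on (bottleneck, length) lexicographic cost
  bott <- rep(Inf, nr * nc); len <- rep(Inf, nr * nc)
  pred <- integer(nr * nc)
  done <- rep(FALSE, nr * nc)
  bott[s] <- v[s]; len[s] <- 0
  repeat {
    active <- which(!done & is.finite(bott))
    if (length(active) == 0) break
    u <- active[order(bott[active], len[active], active)][1]
    if (u == e) break
    done[u] <- TRUE
    i <- (u - 1) %% nr + 1; j <- (u - 1) %/% nr + 1
    for (dj in -1:1) for (di in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
      w <- (jj - 1) * nr + ii
      if (done[w] || is.na(v[w])) next
      nb <- max(bott[u], v[w]); nl <- len[u] + 1
      if (nb < bott[w] || (nb == bott[w] && nl < len[w])) {
        bott[w] <- nb; len[w] <- nl; pred[w] <- u
      }
    }
  }
  if (!is.finite(bott[e])) stop("start and end are not connected on the ",
                                "sampled grid")
  path <- e
  while (path[1] != s) path <- c(pred[path[1]], path)
  i <- (path - 1) %% nr + 1; j <- (path - 1) %/% nr + 1
  nodes <- tibble::tibble(z1 = grid$axes[[1]]$mids[i],
                          z2 = grid$axes[[2]]$mids[j],
                          energy = v[path])
  in_band <- abs(nodes$z1 - nodes$z2) <= delta
  crosses <- any(diff(sign(nodes$z1 - nodes$z2)) != 0)
  label <- if (!any(in_band)) "pathway-I-like knock-on"
           else if (crosses) "pathway-II-like" else "mixed"
  structure(nodes, class = c("path_result", class(nodes)),
            barrier = max(nodes$energy) - nodes$energy[1], label = label)
}

#' Classify a two-ion configuration as pass-by or knock-on
#'
#' Two ions at (nearly) the same axial coordinate -- |z1 - z2| <= delta,
#' boundary inclusive -- are side by side in the pore cross-section
#' ("pass-by", the geometry of the block state); otherwise they are in
#' single file ("knock-on").
#'
#' @param z1,z2 Axial coordinates, A (vectorised).
#' @param delta Same-z tolerance, A (default 1).
#' @return Character vector, "pass-by" or "knock-on".
#' @export
#' @examples
#' classify_pair_configuration(-10, -13, 1) # knock-on: ~3 A apart
classify_pair_configuration <- function(z1, z2, delta = 1.0) {
  stopifnot(all(is.finite(z1)), all(is.finite(z2)))
  ifelse(abs(z1 - z2) <= delta, "pass-by", "knock-on")
}
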