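#' Jarzynski free-energy estimate from a work distribution
#'
#' Applies Jarzynski's equality, exp(-dF/k_B T) = <exp(-W/k_B T)>, to a set
#' of work samples: dF = -k_B T log[(1/Q) sum_q exp(-W_q/k_B T)], computed
#' with an overflow-safe log-sum-exp. The estimate never exceeds the sample
#' mean (Jensen's bound) and is dominated by the low-work tail.
#'
#' @param W Numeric vector of work samples, kcal/mol (Q >= 2 for an
#'   uncertainty; Q >= 1 for the point estimate).
#' @param temperature Temperature, K.
#' @return List with `dF` (kcal/mol), `se` (from [variance_of_estimate()];
#'   NA when Q < 2), `sigma_W`, `Q`.
#' @export
#' @examples
#' estimate_delta_F(c(0, 0, 1.192), 300) # dF ~ 0.203 kcal/mol
estimate_delta_F <- function(W, temperature = 300) {
  if (length(W) < 1 || !is.numeric(W)) stop("empty work distribution")
  b <- 1 / (constants$k_B * temperature)
  m <- max(-b * W)
  dF <- -(m + log(mean(exp(-b * W - m)))) / b
  sig <- if (length(W) >= 2) stats::sd(W) else NA_real_
  list(dF = dF,
       se = if (length(W) >= 2)
         variance_of_estimate(sig, length(W), temperature) else NA_real_,
       sigma_W = sig, Q = length(W))
}

#' Uncertainty of a Jarzynski estimate
#'
#' The standard error attached to each free-energy value:
#' [sigma_W^2/Q + sigma_W^4 (k_B T)^-2 / (2(Q-1))]^(1/2), where sigma_W is
#' the standard deviation of the work distribution and Q its sample count.
#' The second term is the bias-driven contribution that grows with the width
#' of the distribution relative to k_B T.
#'
#' @param sigma_W Standard deviation of the work samples, kcal/mol (>= 0).
#' @param Q Number of work samples (>= 2).
#' @param temperature Temperature, K.
#' @return Standard error in kcal/mol.
#' @export
#' @examples
#' variance_of_estimate(0.596, 100, 300) # ~0.073
variance_of_estimate <- function(sigma_W, Q, temperature = 300) {
  if (Q < 2) stop("Q must be >= 2")
  stopifnot(sigma_W >= 0)
  kt <- constants$k_B * temperature
  sqrt(sigma_W^2 / Q + sigma_W^4 / kt^2 / (2 * (Q - 1)))
}

new_free_energy_profile <- function(df, direction = "inward") {
  structure(df, class = c("free_energy_profile", class(df)),
            direction = direction)
}

#' Assemble a cumulative free-energy profile from per-step estimates
#'
#' Anchors the profile at 0 at the first restraint centre and accumulates
#' the per-step free-energy changes along the schedule; per-step
#' uncertainties combine in quadrature (step-to-step correlations are
#' ignored).
#'
#' @param step_dF Numeric vector of per-switch free-energy changes,
#'   one per switch (length = length(schedule) - 1).
#' @param schedule Numeric vector of restraint centres, A.
#' @param step_se Optional per-switch standard errors.
#' @param direction "inward" or "outward" tag carried on the result.
#' @return A `free_energy_profile` tibble with columns `lambda`, `dF`,
#'   `dF_se`.
#' @export
profile_from_steps <- function(step_dF, schedule, step_se = NULL,
                               direction = "inward") {
  if (length(step_dF) != length(schedule) - 1)
    stop("length mismatch: need one per-step dF per switch ",
         "(length(schedule) - 1)")
  if (is.null(step_se)) step_se <- rep(0, length(step_dF))
  new_free_energy_profile(
    tibble::tibble(lambda = schedule,
                   dF = c(0, cumsum(step_dF)),
                   dF_se = c(0, sqrt(cumsum(step_se^2)))),
    direction = direction)
}

#' Jarzynski free-energy profile from a work ledger
#'
#' The workhorse of the nonequilibrium stage: converts the work ledger of
#' [run_pulling()] into the perturbed Helmholtz free-energy profile
#' ("useful work") dF(lambda), with per-point uncertainties and optional
#' per-ion components.
#'
#' @param ledger Work-ledger tibble (columns replica, step, lambda, dW,
#'   W_cum, and dW_ion<j> for per-ion components), or a `pull_run`.
#' @param temperature Temperature, K.
#' @param method "cumulative" (default) applies Jarzynski's equality to the
#'   cumulative work at each schedule point -- the estimator used throughout
#'   the analysis; "stepwise" estimates each switch independently and
#'   accumulates via [profile_from_steps()].
#' @param per_ion If TRUE and per-ion work columns are present, adds
#'   per-ion component profiles (see [per_ion_profiles()] for the weighting).
#' @param direction Direction tag; inferred from a `pull_run` input.
#' @return A `free_energy_profile` tibble: `lambda`, `dF`, `dF_se`, and
#'   `dF_ion<j>` columns when requested.
#' @export
jarzynski_profile <- function(ledger, temperature = 300,
                              method = c("cumulative", "stepwise"),
                              per_ion = TRUE, direction = NULL) {
  method <- match.arg(method)
  schedule <- NULL
  if (inherits(ledger, "pull_run")) {
    if (is.null(direction)) direction <- ledger$direction
    schedule <- ledger$schedule
    ledger <- ledger$ledger
  }
  if (is.null(direction)) direction <- "inward"
  if (nrow(ledger) == 0) stop("empty work ledger")
  steps <- sort(unique(ledger$step))
  lam <- vapply(steps, function(s) ledger$lambda[ledger$step == s][1],
                numeric(1))
  # schedule = anchor (extrapolated one increment back) + switch targets
  if (is.null(schedule)) {
    anchor <- if (length(lam) >= 2) 2 * lam[1] - lam[2] else lam[1]
    schedule <- c(anchor, lam)
  }
  kt <- constants$k_B * temperature
  est <- lapply(steps, function(s) {
    d <- ledger[ledger$step == s, ]
    W <- if (method == "cumulative") d$W_cum else d$dW
    estimate_delta_F(W, temperature)
  })
  if (method == "cumulative") {
    prof <- tibble::tibble(
      lambda = schedule,
      dF = c(0, vapply(est, `[[`, numeric(1), "dF")),
      dF_se = c(0, vapply(est, `[[`, numeric(1), "se")))
  } else {
    prof <- profile_from_steps(vapply(est, `[[`, numeric(1), "dF"), schedule,
                               vapply(est, `[[`, numeric(1), "se"))
  }
  ion_cols <- grep("^dW_ion", names(ledger), value = TRUE)
  if (per_ion && length(ion_cols) > 0) {
    comp <- per_ion_components(ledger, steps, ion_cols, kt,
                               total = prof$dF[-1])
    for (j in seq_along(ion_cols)) {
      prof[[sub("dW_", "dF_", ion_cols[j])]] <- c(0, comp[, j])
    }
  }
  new_free_energy_profile(prof, direction = direction)
}

# Exponentially weighted per-ion cumulative work with the residual
# (dF - weighted total) split equally, so components sum exactly to dF.
per_ion_components <- function(ledger, steps, ion_cols, kt, total) {
  n_ion <- length(ion_cols)
  out <- matrix(0, nrow = length(steps), ncol = n_ion)
  for (si in seq_along(steps)) {
    d <- ledger[ledger$step <= steps[si], ]
    cum <- dplyr::summarise(
      dplyr::group_by(d, .data$replica),
      W = sum(.data$dW),
      dplyr::across(dplyr::all_of(ion_cols), sum), .groups = "drop")
    lw <- -cum$W / kt
    w <- exp(lw - max(lw)); w <- w / sum(w)
    wmean_ion <- vapply(ion_cols, function(cn) sum(w * cum[[cn]]), numeric(1))
    resid <- total[si] - sum(w * cum$W)
    out[si, ] <- wmean_ion + resid / n_ion
  }
  out
}

#' Per-ion free-energy component profiles
#'
#' Decomposes the total Jarzynski profile into per-ion components: each
#' replica's per-ion cumulative work is averaged under the exponential
#' weights exp(-W/k_B T) computed from the *total* work, and the remaining
#' fluctuation term (the gap between the weighted mean total work and the
#' Jarzynski estimate) is shared equally among ions, so the components sum
#' to the total exactly at every lambda. An alternative that applies
#' Jarzynski's equality to each ion's work independently is available; its
#' components need not sum to the total.
#'
#' @param run A `pull_run` (or ledger tibble with per-ion columns).
#' @param temperature Temperature, K.
#' @param method "weighted" (default, exact-sum decomposition) or
#'   "independent" (per-ion Jarzynski).
#' @return A `free_energy_profile` tibble with `lambda`, `dF`, `dF_se` and
#'   one `dF_ion<j>` column per ion.
#' @export
per_ion_profiles <- function(run, temperature = 300,
                             method = c("weighted", "independent")) {
  method <- match.arg(method)
  ledger <- if (inherits(run, "pull_run")) run$ledger else run
  ion_cols <- grep("^dW_ion", names(ledger), value = TRUE)
  if (length(ion_cols) == 0) stop("ledger has no per-ion work columns")
  if (method == "weighted")
    return(jarzynski_profile(run, temperature, per_ion = TRUE))
  prof <- jarzynski_profile(run, temperature, per_ion = FALSE)
  steps <- sort(unique(ledger$step))
  for (cn in ion_cols) {
    vals <- vapply(steps, function(s) {
      d <- ledger[ledger$step <= s, ]
      cum <- dplyr::summarise(dplyr::group_by(d, .data$replica),
                              Wi = sum(.data[[cn]]), .groups = "drop")
      estimate_delta_F(cum$Wi, temperature)$dF
    }, numeric(1))
    prof[[sub("dW_", "dF_", cn)]] <- c(0, vals)
  }
  prof
}
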