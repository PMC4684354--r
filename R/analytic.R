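#' Steady-state ribosome density of the independent-particle model
#'
#' In the open-boundary model where a ribosome waits an exponential time
#' with mean `dwell[i]` at position `i` and positions do not exclude each
#' other, the stationary density is exactly `flux * dwell[i]`: constant
#' current J through every position.
#'
#' @param dwell_vector Positive numeric vector of per-position mean dwells.
#' @param flux Upstream ribosome flux J (> 0).
#' @return Numeric vector of expected densities.
#' @export
steady_state_density <- function(dwell_vector, flux = 1) {
  if (any(!is.finite(dwell_vector)) || any(dwell_vector <= 0)) {
    stop("dwell times must be strictly positive and finite", call. = FALSE)
  }
  if (!is_number(flux) || flux <= 0) stop("`flux` must be > 0", call. = FALSE)
  flux * dwell_vector
}

#' Evolve expected ribosome density after a dwell-time change
#'
#' Integrates the master equation of the independent-particle model,
#'   drho_i/dt = k_{i-1} rho_{i-1} - k_i rho_i,   k_i = 1/dwell_new[i],
#' with constant upstream inflow `flux` at the first position, starting from
#' the old steady state `rho_i(0) = flux * dwell_old[i]`. The relaxation
#' from the old to the new stationary profile is the advancing, spreading
#' wave of excess (or depleted) density seen downstream of codons whose
#' elongation rate was perturbed.
#'
#' @param dwell_old,dwell_new Positive numeric vectors of equal length
#'   (>= 3): per-position mean dwells before and after the change.
#' @param flux Upstream flux J (> 0).
#' @param times Non-negative, strictly ascending sample times.
#' @return An object of class `DensityTrajectory`: list with `times`,
#'   `positions` (0-based), `density` (matrix, time x position), `flux`,
#'   `dwell_old`, `dwell_new`.
#' @export
evolve_density <- function(dwell_old, dwell_new, flux = 1, times) {
  if (length(dwell_old) != length(dwell_new)) {
    stop("`dwell_old` and `dwell_new` must have the same length", call. = FALSE)
  }
  if (length(dwell_new) < 3L) stop("at least 3 positions required", call. = FALSE)
  if (any(!is.finite(dwell_old)) || any(dwell_old <= 0) ||
      any(!is.finite(dwell_new)) || any(dwell_new <= 0)) {
    stop("dwell times must be strictly positive and finite", call. = FALSE)
  }
  if (!is_number(flux) || flux <= 0) stop("`flux` must be > 0", call. = FALSE)
  times <- as.numeric(times)
  if (length(times) < 1L || any(times < 0) || is.unsorted(times, strictly = TRUE)) {
    stop("`times` must be non-negative and strictly ascending", call. = FALSE)
  }
  k <- 1 / dwell_new
  L <- length(k)
  y0 <- flux * dwell_old
  deriv <- function(t, y, parms) {
    inflow <- c(flux, k[-L] * y[-L])
    list(inflow - k * y)
  }
  t_solve <- if (times[1] == 0) times else c(0, times)
  sol <- deSolve::ode(y = y0, times = t_solve, func = deriv, parms = NULL,
                      method = "lsoda", rtol = 1e-8, atol = 1e-12)
  dens <- unname(sol[match(times, t_solve), -1, drop = FALSE])
  structure(list(times = times, positions = 0:(L - 1L), density = dens,
                 flux = flux, dwell_old = dwell_old, dwell_new = dwell_new),
            class = "DensityTrajectory")
}

#' @export
print.DensityTrajectory <- function(x, ...) {
  cat("DensityTrajectory:", length(x$positions), "positions,",
      length(x$times), "time points (t in [", min(x$times), ",",
      max(x$times), "])\n")
  invisible(x)
}

#' Summarize the relaxation wave of a density trajectory
#'
#' For each time point, measures the excess density relative to the new
#' steady state over positions at and downstream of the perturbed codon:
#' `net_area` is the signed sum of the excess (positive for an enrichment
#' wave after a slow-to-fast change, negative for a depletion wave after a
#' fast-to-slow change), `center` the |excess|-weighted centroid (in codons
#' downstream of the perturbation) and `width` the |excess|-weighted
#' standard deviation. For excess travelling through a uniform fast region
#' of rate `k_f`, `center(t) ~ k_f * t` and `width(t) ~ sqrt(k_f * t)` (the
#' Poisson signature of independent exponential hops).
#'
#' @param trajectory A `DensityTrajectory` from [evolve_density()].
#' @param baseline Reference density vector (default: the new steady state
#'   `flux * dwell_new`).
#' @param origin 0-based index of the perturbed position (default: the
#'   position where |dwell_old - dwell_new| is largest).
#' @return Data.frame with columns `time`, `center`, `width`, `net_area`,
#'   `defined` (`FALSE` with `NA` center/width when there is no excess).
#' @export
wave_summary <- function(trajectory, baseline = NULL, origin = NULL) {
  stopifnot(inherits(trajectory, "DensityTrajectory"))
  if (is.null(baseline)) baseline <- trajectory$flux * trajectory$dwell_new
  if (length(baseline) != length(trajectory$positions)) {
    stop("`baseline` length must match the trajectory positions", call. = FALSE)
  }
  if (is.null(origin)) {
    origin <- trajectory$positions[which.max(abs(trajectory$dwell_old -
                                                 trajectory$dwell_new))]
  }
  down <- trajectory$positions >= origin
  d <- trajectory$positions[down] - origin
  out <- lapply(seq_along(trajectory$times), function(i) {
    exc <- trajectory$density[i, down] - baseline[down]
    w <- abs(exc)
    if (sum(w) <= 1e-12) {
      return(data.frame(time = trajectory$times[i], center = NA_real_,
                        width = NA_real_, net_area = sum(exc), defined = FALSE))
    }
    ctr <- sum(d * w) / sum(w)
    wid <- sqrt(sum(w * (d - ctr)^2) / sum(w))
    data.frame(time = trajectory$times[i], center = ctr, width = wid,
               net_area = sum(exc), defined = TRUE)
  })
  do.call(rbind, out)
}
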