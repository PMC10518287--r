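#' Perfusion resistance trace
#'
#' A time series of baseline-normalised perfusion resistance around a
#' solution switch at time zero, with the pre/post solution compositions
#' attached as metadata (required by the fitting routines to reconstruct
#' the boundary conditions).
#'
#' @param time_min Time in minutes relative to the switch, strictly
#'   increasing; negative times are the pre-switch baseline.
#' @param Rp_norm Normalised perfusion resistance, positive.
#' @param pre,post Lists with `C_is` (mol/m^3), `C_cpa` (mol/m^3) and
#'   `viscosity_ratio` describing the solutions either side of the switch.
#' @param pressure Perfusion pressure, mmHg (metadata only).
#' @return An object of class `perfusion_trace` (a data frame).
#' @export
perfusion_trace <- function(time_min, Rp_norm,
                            pre = list(C_is = 283, C_cpa = 0,
                                       viscosity_ratio = 1),
                            post = list(C_is = 583, C_cpa = 0,
                                        viscosity_ratio = 1),
                            pressure = 40) {
  stopifnot(length(time_min) == length(Rp_norm))
  if (any(diff(time_min) <= 0)) stop("time must be strictly increasing")
  if (any(Rp_norm <= 0)) stop("Rp_norm must be positive")
  for (s in list(pre, post))
    stopifnot(is.list(s), all(c("C_is", "C_cpa", "viscosity_ratio") %in%
                                names(s)))
  base <- Rp_norm[time_min < 0]
  if (length(base) >= 3 && abs(mean(base) - 1) > 0.05)
    stop("baseline window mean deviates from 1 by more than 5%; normalise the trace first")
  structure(data.frame(time_min = time_min, Rp_norm = Rp_norm),
            class = c("perfusion_trace", "data.frame"),
            pre = pre, post = post, pressure = pressure)
}

#' Steady resistance over a terminal window
#'
#' Mean of the trace over its last `window` minutes, used to extract the
#' stabilised plateau resistance of a stepped-osmolarity perfusion. A
#' drift guard rejects windows whose fitted slope is still large.
#'
#' @param trace A [perfusion_trace()] or data frame with `time_min`,
#'   `Rp_norm`.
#' @param window Window length, min.
#' @param max_drift Largest admissible |slope| of the windowed linear fit,
#'   per minute, relative to the window mean.
#' @return The windowed mean resistance.
#' @export
steady_resistance <- function(trace, window = 3, max_drift = 0.01) {
  tmax <- max(trace$time_min)
  w <- trace$time_min >= tmax - window
  if (sum(w) < 3) stop("terminal window holds fewer than 3 samples")
  y <- trace$Rp_norm[w]; x <- trace$time_min[w]
  m <- mean(y)
  slope <- stats::coef(stats::lm(y ~ x))[[2L]]
  if (abs(slope / m) > max_drift)
    stop(sprintf("resistance still drifting (%.3f/min relative); extend the perfusion",
                 slope / m))
  m
}
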