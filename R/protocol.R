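#' Ramp-hold-step CPA loading protocol
#'
#' Arterial boundary schedule for perfusion loading: a CPA-free carrier
#' flush, a linear concentration ramp, a constant plateau, then a step to
#' full strength held either for a fixed duration or (`"auto"`) until the
#' tissue concentration reaches a target (see [simulate_loading()]).
#' Time zero is the start of the ramp; the flush occupies negative time.
#'
#' @param ramp_rate Ramp rate, mM/min.
#' @param ramp_duration Ramp duration, min. The plateau concentration is
#'   `ramp_rate * ramp_duration / 1000` M and must not exceed
#'   `full_strength_conc`.
#' @param plateau_duration Plateau duration, min.
#' @param full_strength_conc Full-strength CPA concentration, M.
#' @param full_strength_duration Duration of the full-strength hold, min,
#'   or `"auto"` to terminate when the tissue reaches a target
#'   concentration.
#' @param flush_duration Carrier flush before the ramp, min.
#' @param pressure_main Perfusion pressure up to the step, mmHg.
#' @param pressure_full Perfusion pressure during the full-strength hold,
#'   mmHg (raised to maintain flow against the more viscous solution; it
#'   does not enter the transport model when `hydraulic_dP = 0`).
#' @param carrier_osmolarity Impermeant osmolarity of the carrier, mOsm
#'   (default 330, the CPA-vehicle carrier).
#' @return An object of class `loading_protocol`.
#' @examples
#' existing_protocol()           # ramp to 5 M over 100 min, +10 min, 25 min at 8.4 M
#' build_protocol(62, 80, 5)     # the optimised schedule, auto-terminated hold
#' @export
build_protocol <- function(ramp_rate, ramp_duration, plateau_duration,
                           full_strength_conc = 8.4,
                           full_strength_duration = "auto",
                           flush_duration = 20,
                           pressure_main = 40, pressure_full = 60,
                           carrier_osmolarity = 330) {
  stopifnot(ramp_rate >= 0, ramp_duration >= 0, plateau_duration >= 0,
            flush_duration >= 0, full_strength_conc >= 0)
  plateau_conc <- ramp_rate * ramp_duration / 1000
  if (plateau_conc > full_strength_conc + 1e-9)
    stop(sprintf("implied plateau concentration %.2f M exceeds full strength %.2f M",
                 plateau_conc, full_strength_conc))
  auto <- identical(full_strength_duration, "auto")
  if (!auto) stopifnot(is.numeric(full_strength_duration),
                       full_strength_duration >= 0)
  structure(list(ramp_rate = ramp_rate, ramp_duration = ramp_duration,
                 plateau_duration = plateau_duration,
                 plateau_conc = plateau_conc,
                 full_strength_conc = full_strength_conc,
                 full_strength_duration = if (auto) NA_real_ else
                   full_strength_duration,
                 auto_hold = auto,
                 flush_duration = flush_duration,
                 pressure_main = pressure_main,
                 pressure_full = pressure_full,
                 carrier_osmolarity = carrier_osmolarity),
            class = "loading_protocol")
}

#' The previously validated (existing) loading protocol
#'
#' Ramp from 0 to 5 M at 50 mM/min over 100 min, hold 10 min at 5 M, then
#' step to 8.4 M for a fixed 25 min: 135 min of loading after the flush.
#'
#' @param ... Overrides passed to [build_protocol()].
#' @export
existing_protocol <- function(...) {
  args <- list(ramp_rate = 50, ramp_duration = 100, plateau_duration = 10,
               full_strength_duration = 25)
  args[names(list(...))] <- list(...)
  do.call(build_protocol, args)
}

#' @export
print.loading_protocol <- function(x, ...) {
  hold <- if (x$auto_hold) "auto" else sprintf("%.1f min", x$full_strength_duration)
  cat(sprintf(
    "Ramp-hold-step loading protocol\n  %g mM/min for %g min (plateau %.2f M), hold %g min, step to %g M (%s)\n",
    x$ramp_rate, x$ramp_duration, x$plateau_conc, x$plateau_duration,
    x$full_strength_conc, hold))
  cat(sprintf("  flush %g min at %g mOsm; pressure %g/%g mmHg\n",
              x$flush_duration, x$carrier_osmolarity, x$pressure_main,
              x$pressure_full))
  invisible(x)
}

#' Arterial CPA concentration of a protocol
#'
#' @param protocol A [build_protocol()].
#' @param t_min Time in minutes from ramp start (vectorised); the flush is
#'   at negative times.
#' @return Arterial CPA concentration, M.
#' @export
arterial_concentration <- function(protocol, t_min) {
  p <- protocol
  t_step <- p$ramp_duration + p$plateau_duration
  ifelse(t_min < 0, 0,
         ifelse(t_min < p$ramp_duration, p$ramp_rate * t_min / 1000,
                ifelse(t_min < t_step, p$plateau_conc,
                       p$full_strength_conc)))
}

#' Arterial pressure schedule of a protocol
#'
#' @inheritParams arterial_concentration
#' @return Pressure, mmHg.
#' @export
arterial_pressure <- function(protocol, t_min) {
  t_step <- protocol$ramp_duration + protocol$plateau_duration
  ifelse(t_min < t_step, protocol$pressure_main, protocol$pressure_full)
}
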