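#' Osmotic volume-excursion constraints
#'
#' A loading protocol is osmotically admissible if the active volume never
#' falls below a hard floor (irreversible damage) and spends at most a
#' bounded time below a softer stress floor. Floors are fractions of the
#' stabilised end-of-flush baseline volume.
#'
#' @param hard_floor Hard minimum volume fraction (default 0.45).
#' @param stress_floor Osmotic-stress threshold (default 0.73).
#' @param stress_time_max Longest admissible time below the stress floor,
#'   min (default 25).
#' @param stress_mode `"cumulative"` (default) counts total time below the
#'   stress floor; `"contiguous"` counts the longest single excursion.
#' @return An object of class `osmotic_constraints`.
#' @export
osmotic_constraints <- function(hard_floor = 0.45, stress_floor = 0.73,
                                stress_time_max = 25,
                                stress_mode = c("cumulative", "contiguous")) {
  if (!(0 < hard_floor && hard_floor < stress_floor && stress_floor < 1))
    stop("need 0 < hard_floor < stress_floor < 1")
  structure(list(hard_floor = hard_floor, stress_floor = stress_floor,
                 stress_time_max = stress_time_max,
                 stress_mode = match.arg(stress_mode)),
            class = "osmotic_constraints")
}

#' Check a simulation against the osmotic constraints
#'
#' @param sim A `cpa_simulation` from [simulate_loading()].
#' @param constraints An [osmotic_constraints()].
#' @return A list with `feasible`, `min_Vfrac` (relative to the baseline
#'   volume) and `time_below_stress_floor` (min).
#' @export
check_osmotic <- function(sim, constraints = osmotic_constraints()) {
  b <- attr(sim, "baseline_V_frac")
  if (is.null(b)) b <- 1
  keep <- sim$time_min >= 0
  v <- sim$V_frac[keep] / b
  t <- sim$time_min[keep]
  below <- v < constraints$stress_floor
  dt <- diff(t)
  t_below <- if (constraints$stress_mode == "cumulative") {
    sum(dt[below[-1L]])
  } else {
    r <- rle(below)
    if (!any(r$values)) 0 else {
      ends <- cumsum(r$lengths)
      starts <- c(1L, utils::head(ends, -1L) + 1L)
      max(t[ends[r$values]] - t[starts[r$values]])
    }
  }
  list(feasible = min(v) >= constraints$hard_floor &&
         t_below <= constraints$stress_time_max,
       min_Vfrac = min(v),
       time_below_stress_floor = t_below)
}

#' Grid of candidate ramp-hold-step protocols
#'
#' @param ramp_rate Ramp rates to test, mM/min.
#' @param ramp_duration Ramp durations, min.
#' @param plateau_duration Plateau durations, min.
#' @param plateau_conc_range Admissible plateau concentrations, M;
#'   combinations outside the range are excluded.
#' @return An object of class `optimization_grid`.
#' @export
optimization_grid <- function(ramp_rate = seq(40, 70, by = 1),
                              ramp_duration = seq(70, 120, by = 5),
                              plateau_duration = seq(4, 20, by = 1),
                              plateau_conc_range = c(3, 7)) {
  structure(list(ramp_rate = ramp_rate, ramp_duration = ramp_duration,
                 plateau_duration = plateau_duration,
                 plateau_conc_range = plateau_conc_range),
            class = "optimization_grid")
}

#' Grid search for the minimum-toxicity loading protocol
#'
#' Simulates every ramp-rate x ramp-duration x plateau-duration
#' combination with an auto-terminated full-strength hold, excludes
#' infeasible points (plateau concentration outside its bounds, osmotic
#' violation, target unreachable) and returns the feasible protocol with
#' the smallest cumulative toxicity cost. Ties are broken by shortest
#' total protocol, then lowest ramp rate. The search is fully
#' deterministic.
#'
#' If `target_conc` is `NULL` the target is set self-consistently to the
#' simulated tissue endpoint of the existing (experimentally vitrifiable)
#' protocol under the same parameters.
#'
#' @param grid An [optimization_grid()].
#' @param geom,mem,tox,settings Model parameter objects.
#' @param constraints An [osmotic_constraints()].
#' @param target_conc Vitrifiable tissue concentration target, M.
#' @param M_iso Isotonic osmolarity, mol/m^3.
#' @param max_full_strength Cap on the auto hold, min.
#' @return An object of class `protocol_optimization`: list with `records`
#'   (one row per grid point), `best` (the argmin row), `best_protocol`,
#'   `per_rate` (minimum feasible J_tox per ramp rate) and `target_conc`.
#' @export
optimize_protocol <- function(grid = optimization_grid(),
                              geom = krogh_geometry(),
                              mem = membrane_params(),
                              tox = toxicity_params(),
                              settings = sim_settings(output_dt = 5),
                              constraints = osmotic_constraints(),
                              target_conc = NULL, M_iso = 290,
                              max_full_strength = 60) {
  if (is.null(target_conc)) {
    ref <- simulate_loading(existing_protocol(), geom, mem, tox, settings,
                            M_iso = M_iso)
    target_conc <- attr(ref, "C_end")
  }
  combos <- expand.grid(ramp_rate = grid$ramp_rate,
                        ramp_duration = grid$ramp_duration,
                        plateau_duration = grid$plateau_duration,
                        KEEP.OUT.ATTRS = FALSE)
  plat <- combos$ramp_rate * combos$ramp_duration / 1000
  rec <- cbind(combos, plateau_conc = plat,
               feasible = FALSE, J_tox = NA_real_,
               full_strength_min = NA_real_, min_Vfrac = NA_real_,
               time_below = NA_real_)
  in_range <- plat >= grid$plateau_conc_range[1L] &
    plat <= grid$plateau_conc_range[2L]
  for (i in which(in_range)) {
    prot <- build_protocol(rec$ramp_rate[i], rec$ramp_duration[i],
                           rec$plateau_duration[i])
    sim <- simulate_loading(prot, geom, mem, tox, settings, M_iso = M_iso,
                            target_conc = target_conc,
                            max_full_strength = max_full_strength)
    chk <- check_osmotic(sim, constraints)
    rec$J_tox[i] <- attr(sim, "J_tox")
    rec$full_strength_min[i] <- attr(sim, "full_strength_duration")
    rec$min_Vfrac[i] <- chk$min_Vfrac
    rec$time_below[i] <- chk$time_below_stress_floor
    rec$feasible[i] <- chk$feasible && attr(sim, "target_reached")
  }
  feas <- rec[rec$feasible, , drop = FALSE]
  if (nrow(feas) == 0) stop("no feasible protocol on the grid")
  total <- feas$ramp_duration + feas$plateau_duration +
    feas$full_strength_min
  ord <- order(feas$J_tox, total, feas$ramp_rate)
  best <- feas[ord[1L], , drop = FALSE]
  per_rate <- do.call(rbind, lapply(split(feas, feas$ramp_rate), function(d)
    data.frame(ramp_rate = d$ramp_rate[1L], min_J_tox = min(d$J_tox))))
  rownames(per_rate) <- NULL
  structure(list(records = rec, best = best,
                 best_protocol = build_protocol(best$ramp_rate,
                                                best$ramp_duration,
                                                best$plateau_duration),
                 per_rate = per_rate, target_conc = target_conc),
            class = "protocol_optimization")
}

#' @export
print.protocol_optimization <- function(x, ...) {
  b <- x$best
  cat("Loading-protocol grid optimization\n")
  cat(sprintf("  %d grid points, %d feasible; target %.3f M\n",
              nrow(x$records), sum(x$records$feasible), x$target_conc))
  cat(sprintf("  argmin: %g mM/min, ramp %g min, plateau %g min -> J_tox %.4f, hold %.1f min\n",
              b$ramp_rate, b$ramp_duration, b$plateau_duration, b$J_tox,
              b$full_strength_min))
  invisible(x)
}
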