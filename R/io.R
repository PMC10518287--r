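#' Read a perfusion trace from delimited text
#'
#' Accepts either a pre-normalised trace (`time_min`, `Rp_norm`) or raw
#' pressure/flow columns (`time_min`, `pressure_mmHg`, `flow_mL_min`),
#' from which the perfusion resistance Rp = P/Q is computed and normalised
#' to the mean over the declared baseline window (times < 0).
#'
#' @param path CSV file with a header row.
#' @param pre,post Switch solution metadata attached to the trace (see
#'   [perfusion_trace()]).
#' @param pressure Perfusion pressure, mmHg.
#' @return A [perfusion_trace()].
#' @export
read_trace <- function(path,
                       pre = list(C_is = 283, C_cpa = 0, viscosity_ratio = 1),
                       post = list(C_is = 583, C_cpa = 0,
                                   viscosity_ratio = 1),
                       pressure = 40) {
  d <- utils::read.csv(path)
  if (!"time_min" %in% names(d))
    stop("trace file must have a time_min column")
  if (any(diff(d$time_min) <= 0))
    stop("time_min must be strictly increasing")
  if ("Rp_norm" %in% names(d)) {
    rp <- d$Rp_norm
  } else if (all(c("pressure_mmHg", "flow_mL_min") %in% names(d))) {
    if (any(d$flow_mL_min <= 0)) stop("flow must be positive")
    rp_abs <- d$pressure_mmHg / d$flow_mL_min
    base <- rp_abs[d$time_min < 0]
    if (length(base) < 1)
      stop("pressure/flow traces need a pre-switch baseline window (times < 0)")
    rp <- rp_abs / mean(base)
  } else {
    stop("need either Rp_norm or pressure_mmHg + flow_mL_min columns")
  }
  perfusion_trace(d$time_min, rp, pre = pre, post = post,
                  pressure = pressure)
}

#' Write a perfusion trace to CSV
#'
#' @param trace A [perfusion_trace()].
#' @param path Output file.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace)[, c("time_min", "Rp_norm")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Export a loading simulation as delimited text
#'
#' Columns: `time_min`, `C_art_M`, `V_frac`, `C_tissue_M`, `rc_um`,
#' `R_norm`, `Rp_norm`, `Jtox_cum`.
#'
#' @param sim A `cpa_simulation`.
#' @param path Output CSV file.
#' @export
export_simulation <- function(sim, path) {
  utils::write.csv(as.data.frame(sim), path, row.names = FALSE)
  invisible(path)
}

.PARAM_KEYS <- c("r_c0_m", "r_k_m", "l_c_m", "r_a_m",
                 "Lp_m3_per_N_s", "omega_mol_per_N_s", "sigma",
                 "alpha", "beta_per_min_Malpha",
                 "temperature_K", "M_iso_mol_m3", "notes")

#' Write a parameter set as JSON with unit-suffixed keys
#'
#' @param params A list as from [default_parameters()].
#' @param path Output JSON file.
#' @param notes Optional provenance notes (e.g. fitted-from file, seed).
#' @export
write_parameters <- function(params, path, notes = NULL) {
  g <- params$geometry; m <- params$membrane; x <- params$toxicity
  obj <- list(r_c0_m = g$r_c0, r_k_m = g$r_k, l_c_m = g$l_c, r_a_m = g$r_a,
              Lp_m3_per_N_s = m$L_p, omega_mol_per_N_s = m$omega,
              sigma = m$sigma, alpha = x$alpha,
              beta_per_min_Malpha = x$beta,
              temperature_K = params$settings$temperature,
              M_iso_mol_m3 = params$M_iso)
  if (!is.null(notes)) obj$notes <- notes
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a unit-suffixed JSON parameter file
#'
#' Unknown keys are rejected so that silently mis-named (hence mis-united)
#' parameters cannot slip through.
#'
#' @param path JSON file written by [write_parameters()].
#' @return A list as from [default_parameters()].
#' @export
read_parameters <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(obj), .PARAM_KEYS)
  if (length(unknown))
    stop("unknown parameter keys: ", paste(unknown, collapse = ", "))
  need <- setdiff(.PARAM_KEYS, c("notes"))
  missing <- setdiff(need, names(obj))
  if (length(missing))
    stop("missing parameter keys: ", paste(missing, collapse = ", "))
  list(geometry = krogh_geometry(obj$r_c0_m, obj$r_k_m, obj$l_c_m,
                                 obj$r_a_m),
       membrane = membrane_params(obj$Lp_m3_per_N_s,
                                  obj$omega_mol_per_N_s, obj$sigma),
       toxicity = toxicity_params(obj$alpha, obj$beta_per_min_Malpha),
       settings = sim_settings(temperature = obj$temperature_K),
       M_iso = obj$M_iso_mol_m3)
}
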