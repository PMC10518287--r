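#' Capillary membrane transport parameters
#'
#' The Kedem-Katchalsky description of coupled water and solute transport
#' across the capillary membrane uses three parameters: the hydraulic
#' conductivity `L_p`, the CPA (solute) permeability `omega`, and the
#' reflection coefficient `sigma` (1 = membrane rejects the CPA completely,
#' 0 = CPA passes as freely as water). Defaults are the perfusion-derived
#' means for the rat kidney at 4 degC with the VMP cocktail treated as a
#' single permeant species.
#'
#' @param L_p Hydraulic conductivity, m^3/(N s).
#' @param omega CPA permeability, mol/(N s).
#' @param sigma Reflection coefficient, dimensionless in \[0, 1\].
#' @return An object of class `membrane_params`.
#' @export
membrane_params <- function(L_p = 1.5e-14, omega = 7.0e-13, sigma = 0.10) {
  stopifnot(length(L_p) == 1L, length(omega) == 1L, length(sigma) == 1L)
  if (!(L_p > 0)) stop("L_p must be positive")
  if (omega < 0) stop("omega must be non-negative")
  if (sigma < 0 || sigma > 1) stop("sigma must lie in [0, 1]")
  structure(list(L_p = L_p, omega = omega, sigma = sigma),
            class = "membrane_params")
}

#' Power-law toxicity parameters
#'
#' The toxicity rate at CPA concentration C (mol/L) is \eqn{k = \beta C^\alpha}
#' per minute; viability after an exposure is \eqn{\exp(-\int k\,dt)}.
#' Defaults are the slice-calibrated values for VMP at 4 degC.
#'
#' @param alpha Dimensionless exponent, > 0.
#' @param beta Rate prefactor, 1/(min M^alpha), > 0.
#' @param temperature_label Free-text label for the calibration temperature.
#' @return An object of class `toxicity_params`.
#' @export
toxicity_params <- function(alpha = 3.12, beta = 9.39e-6,
                            temperature_label = "4C") {
  if (!(alpha > 0) || !(beta > 0)) stop("alpha and beta must be positive")
  structure(list(alpha = alpha, beta = beta,
                 temperature_label = temperature_label),
            class = "toxicity_params")
}

#' Simulation settings
#'
#' @param temperature Absolute temperature, K (default 277.15, i.e. 4 degC,
#'   the hypothermic perfusion temperature).
#' @param gas_constant Universal gas constant, J/(mol K).
#' @param hydraulic_dP Transmembrane hydraulic pressure P_f - P_t, Pa.
#'   Default 0: at molar CPA concentrations the osmotic term (about 2.3 MPa
#'   per mol/L) dwarfs perfusion pressures (40 mmHg is about 5.3 kPa), and
#'   the interstitial pressure is not observable from perfusion data.
#' @param surface_mode `"fixed"` evaluates the membrane exchange area at the
#'   isotonic capillary radius (the endothelial wall area is a material
#'   property of the vessel and does not grow when the lumen dilates as the
#'   tissue shrinks); `"instantaneous"` tracks the current lumen radius.
#' @param rel_tol,abs_tol Integrator tolerances. `abs_tol = NULL` picks
#'   scale-aware defaults from the geometry.
#' @param output_dt Output grid spacing, s.
#' @return An object of class `sim_settings`.
#' @export
sim_settings <- function(temperature = 277.15, gas_constant = 8.314,
                         hydraulic_dP = 0,
                         surface_mode = c("fixed", "instantaneous"),
                         rel_tol = 1e-8, abs_tol = NULL, output_dt = 1) {
  surface_mode <- match.arg(surface_mode)
  if (!(temperature > 0)) stop("temperature must be positive")
  if (!(output_dt > 0)) stop("output_dt must be positive")
  structure(list(temperature = temperature, gas_constant = gas_constant,
                 hydraulic_dP = hydraulic_dP, surface_mode = surface_mode,
                 rel_tol = rel_tol, abs_tol = abs_tol, output_dt = output_dt),
            class = "sim_settings")
}

#' Arterial boundary state
#'
#' Composition and pressure of the fluid in the capillary, taken equal to
#' the arterial inlet (no axial depletion along the capillary).
#'
#' @param C_cpa_f Arterial CPA concentration, mol/m^3.
#' @param C_is_f Arterial impermeant-solute concentration, mol/m^3.
#' @param pressure Arterial perfusion pressure, Pa.
#' @param viscosity_ratio Perfusate viscosity relative to baseline carrier.
#' @return An object of class `boundary_state`.
#' @export
boundary_state <- function(C_cpa_f = 0, C_is_f = 290, pressure = 5333,
                           viscosity_ratio = 1) {
  if (C_cpa_f < 0 || C_is_f < 0) stop("concentrations must be non-negative")
  if (!(viscosity_ratio > 0)) stop("viscosity_ratio must be positive")
  structure(list(C_cpa_f = C_cpa_f, C_is_f = C_is_f, pressure = pressure,
                 viscosity_ratio = viscosity_ratio),
            class = "boundary_state")
}

#' Tissue state of one Krogh unit
#'
#' State variables are the active volume and the amounts of CPA and
#' impermeant solute; concentrations are derived as amount over volume.
#'
#' @param V Active volume, m^3.
#' @param n_cpa CPA amount, mol.
#' @param n_is Impermeant amount, mol (conserved).
#' @return An object of class `tissue_state` with derived concentrations
#'   `C_cpa_t` and `C_is_t` (mol/m^3).
#' @export
tissue_state <- function(V, n_cpa, n_is) {
  if (!all(is.finite(c(V, n_cpa, n_is)))) stop("non-finite tissue state")
  if (!(V > 0)) stop("active volume must be positive")
  if (n_cpa < 0) stop("CPA amount must be non-negative")
  structure(list(V = V, n_cpa = n_cpa, n_is = n_is,
                 C_cpa_t = n_cpa / V, C_is_t = n_is / V),
            class = "tissue_state")
}

#' Default whole-organ parameter set
#'
#' Geometry, membrane, toxicity and settings objects bundled together, at
#' the rat-kidney reference values used throughout the package.
#'
#' @param M_iso Isotonic osmolarity, mol/m^3.
#' @return A list with elements `geometry`, `membrane`, `toxicity`,
#'   `settings` and `M_iso`.
#' @export
default_parameters <- function(M_iso = 290) {
  list(geometry = krogh_geometry(), membrane = membrane_params(),
       toxicity = toxicity_params(), settings = sim_settings(),
       M_iso = M_iso)
}

# unit conversions used at the interface between experiment-facing units
# (min, M, mmHg) and the SI internals
.MMHG_PA <- 133.322
mmHg_to_Pa <- function(x) x * .MMHG_PA
M_to_molm3 <- function(x) x * 1000
molm3_to_M <- function(x) x / 1000
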