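#' Krogh unit geometry
#'
#' The organ is modelled as many identical hexagonal-prism Krogh units in
#' parallel, each a central capillary surrounded by tissue. `r_k` is the
#' apothem of the full hexagonal prism (half the intercapillary distance),
#' `r_a` the apothem of the smaller hexagonal prism holding the osmotically
#' active volume, and `r_c0` the capillary radius under isotonic conditions.
#'
#' The initial active volume of one unit is
#' \deqn{V_0 = l_c (2\sqrt{3}\, r_a^2 - \pi r_{c0}^2)}
#' and must be positive, which requires \eqn{r_a > 0.9523\, r_{c0}}.
#'
#' @param r_c0 Initial (isotonic) capillary radius, m.
#' @param r_k Apothem of the hexagonal Krogh prism, m.
#' @param l_c Capillary length, m.
#' @param r_a Apothem of the active-volume hexagon, m. The default is the
#'   perfusion-derived mean for the rat kidney.
#' @return An object of class `krogh_geometry`.
#' @examples
#' geom <- krogh_geometry()
#' active_volume(geom)   # ~1.28e-15 m^3
#' @export
krogh_geometry <- function(r_c0 = 3e-6, r_k = 7.5e-6, l_c = 55e-6,
                           r_a = 3.86e-6) {
  stopifnot(is.numeric(r_c0), is.numeric(r_k), is.numeric(l_c), is.numeric(r_a),
            length(r_c0) == 1L, length(r_k) == 1L, length(l_c) == 1L,
            length(r_a) == 1L)
  if (!(r_c0 > 0 && l_c > 0))
    stop("r_c0 and l_c must be positive")
  if (!(r_c0 < r_a && r_a <= r_k))
    stop("geometry requires 0 < r_c0 < r_a <= r_k")
  g <- structure(list(r_c0 = r_c0, r_k = r_k, l_c = l_c, r_a = r_a),
                 class = "krogh_geometry")
  if (active_volume(g) <= 0)
    stop("initial active volume is non-positive; increase r_a or decrease r_c0")
  g
}

#' @export
print.krogh_geometry <- function(x, ...) {
  cat("Krogh unit geometry\n")
  cat(sprintf("  r_c0 = %.3g um, r_k = %.3g um, r_a = %.3g um, l_c = %.3g um\n",
              x$r_c0 * 1e6, x$r_k * 1e6, x$r_a * 1e6, x$l_c * 1e6))
  cat(sprintf("  V0 = %.4g m^3, V_b = %.3f\n", active_volume(x),
              inactive_fraction(x$r_a, x$r_k, x$r_c0)))
  invisible(x)
}

#' Initial active volume of one Krogh unit
#'
#' @param geom A [krogh_geometry()].
#' @return Volume in m^3.
#' @export
active_volume <- function(geom) {
  geom$l_c * (2 * sqrt(3) * geom$r_a^2 - pi * geom$r_c0^2)
}

# hexagonal cross-section area of the active prism, m^2
.active_section <- function(geom) 2 * sqrt(3) * geom$r_a^2

#' Capillary radius from active volume
#'
#' The outer boundary of the Krogh unit is fixed; when the tissue shrinks or
#' swells the capillary lumen takes up the difference:
#' \deqn{r_c = \sqrt{(2\sqrt{3} r_a^2 - V/l_c)/\pi}}
#'
#' @param V Active volume, m^3 (vectorised).
#' @param geom A [krogh_geometry()].
#' @return Capillary radius, m.
#' @examples
#' geom <- krogh_geometry()
#' capillary_radius(active_volume(geom), geom)  # r_c0
#' @export
capillary_radius <- function(V, geom) {
  tsr <- .active_section(geom)
  if (any(!is.finite(V)) || any(V <= 0) || any(V / geom$l_c >= tsr))
    stop("active volume outside geometric range (0, 2*sqrt(3)*r_a^2*l_c)")
  sqrt((tsr - V / geom$l_c) / pi)
}

#' Structural resistance, normalised
#'
#' Laminar (Poiseuille) flow in the capillary makes the vascular structural
#' resistance of the organ proportional to \eqn{r_c^{-4}}; normalising by a
#' reference radius removes the unknown number of Krogh units and the
#' capillary length:
#' \deqn{R/R_{ref} = (r_{c,ref}/r_c)^4}
#'
#' @param r_c Capillary radius, m (vectorised).
#' @param geom A [krogh_geometry()].
#' @param r_c_ref Reference radius for normalisation; defaults to the
#'   isotonic radius `geom$r_c0`.
#' @return Dimensionless normalised structural resistance.
#' @export
structural_resistance_norm <- function(r_c, geom, r_c_ref = geom$r_c0) {
  if (any(r_c <= 0)) stop("capillary radius must be positive")
  (r_c_ref / r_c)^4
}

#' Perfusion resistance, normalised
#'
#' Perfusion resistance is pressure over flow and therefore carries the
#' perfusate viscosity on top of the structural (geometric) resistance.
#'
#' @param R_norm Normalised structural resistance.
#' @param viscosity_ratio Perfusate viscosity relative to the baseline
#'   carrier.
#' @return Normalised perfusion resistance.
#' @export
perfusion_resistance_norm <- function(R_norm, viscosity_ratio) {
  if (any(R_norm <= 0) || any(viscosity_ratio <= 0))
    stop("R_norm and viscosity_ratio must be positive")
  viscosity_ratio * R_norm
}

#' Osmotically inactive volume fraction of the Krogh unit
#'
#' Fraction of the tissue volume (cells plus interstitium, excluding the
#' capillary lumen) that does not take part in osmotic water exchange:
#' \deqn{V_b = \frac{2\sqrt{3}(r_k^2 - r_a^2)}{2\sqrt{3} r_k^2 - \pi r_{c0}^2}}
#'
#' @param r_a Active-volume apothem, m.
#' @param r_k Krogh unit apothem, m.
#' @param r_c0 Isotonic capillary radius, m.
#' @return Dimensionless fraction in \[0, 1).
#' @export
inactive_fraction <- function(r_a, r_k, r_c0) {
  if (!(r_c0 < r_a && r_a <= r_k))
    stop("inactive_fraction requires r_c0 < r_a <= r_k")
  2 * sqrt(3) * (r_k^2 - r_a^2) / (2 * sqrt(3) * r_k^2 - pi * r_c0^2)
}

#' Equilibrium active volume under a CPA-free perfusate
#'
#' Ideal (Boyle van't Hoff) osmometry: at steady state with an impermeant
#' osmolarity `M` the active volume is \eqn{V = (M_{iso}/M) V_0}.
#'
#' @param M Perfusate osmolarity, mol/m^3 (vectorised).
#' @param M_iso Isotonic osmolarity, mol/m^3 (default 290).
#' @param V0 Isotonic active volume, m^3.
#' @return Equilibrium volume, m^3.
#' @export
equilibrium_volume <- function(M, M_iso = 290, V0) {
  if (any(M <= 0)) stop("osmolarity must be positive")
  (M_iso / M) * V0
}

#' Steady-state normalised structural resistance at a given osmolarity
#'
#' Chains the equilibrium volume, the volume-radius relation and the
#' fourth-power resistance law to predict the stabilised resistance of an
#' organ perfused with a CPA-free solution of osmolarity `M`, normalised to
#' the isotonic resistance.
#'
#' @inheritParams equilibrium_volume
#' @param geom A [krogh_geometry()].
#' @return Normalised structural resistance (vectorised over `M`).
#' @export
steady_state_resistance <- function(M, geom, M_iso = 290) {
  V <- equilibrium_volume(M, M_iso, active_volume(geom))
  structural_resistance_norm(capillary_radius(V, geom), geom)
}
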