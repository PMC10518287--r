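#' Configuration for the synthetic-data generators
#'
#' The generators replay the package's forward models at a chosen "true"
#' parameter set and overlay seeded noise, producing datasets shaped like
#' the perfusion and slice experiments so that every estimation stage can
#' be exercised without laboratory data. Noise defaults: multiplicative
#' Gaussian with 2% CV on resistances (instrument-like), additive Gaussian
#' with sd 0.05 on viability fractions (assay-like).
#'
#' @param geometry,membrane,toxicity True parameter objects.
#' @param resistance_cv Coefficient of variation of resistance noise.
#' @param viability_sd Standard deviation of viability noise.
#' @param seed Integer seed recorded in every output.
#' @param M_iso Isotonic osmolarity, mol/m^3.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(geometry = krogh_geometry(),
                         membrane = membrane_params(),
                         toxicity = toxicity_params(),
                         resistance_cv = 0.02, viability_sd = 0.05,
                         seed = 1, M_iso = 290) {
  stopifnot(resistance_cv >= 0, viability_sd >= 0)
  structure(list(geometry = geometry, membrane = membrane,
                 toxicity = toxicity, resistance_cv = resistance_cv,
                 viability_sd = viability_sd, seed = as.integer(seed),
                 M_iso = M_iso),
            class = "synth_config")
}

#' Synthetic solution-switch resistance trace
#'
#' Forward-simulates a solution-switch perfusion (impermeant challenge:
#' carrier to carrier + 300 mM lactose, 15 min; CPA challenge: carrier to
#' 25% VMP = 2.1 M, 30 min) and samples the normalised perfusion
#' resistance with multiplicative Gaussian noise.
#'
#' @param config A [synth_config()].
#' @param challenge `"impermeant"` or `"cpa"`.
#' @param sample_dt Sampling interval, min.
#' @param viscosity_ratio Post-switch viscosity ratio for the CPA
#'   challenge.
#' @return A [perfusion_trace()] with the seed in `attr(, "seed")`.
#' @export
gen_resistance_trace <- function(config = synth_config(),
                                 challenge = c("impermeant", "cpa"),
                                 sample_dt = 0.25, viscosity_ratio = 1.3) {
  challenge <- match.arg(challenge)
  pre <- list(C_is = 283, C_cpa = 0, viscosity_ratio = 1)
  post <- if (challenge == "impermeant")
    list(C_is = 583, C_cpa = 0, viscosity_ratio = 1)
  else
    list(C_is = 283, C_cpa = 2100, viscosity_ratio = viscosity_ratio)
  dur <- if (challenge == "impermeant") 15 else 30
  tr <- simulate_switch(pre, post, duration_min = dur,
                        geom = config$geometry, mem = config$membrane,
                        M_iso = config$M_iso, baseline_min = 2,
                        sample_dt = sample_dt)
  if (config$resistance_cv > 0) {
    set.seed(config$seed)
    post_sw <- tr$time_min >= 0
    tr$Rp_norm[post_sw] <- tr$Rp_norm[post_sw] *
      (1 + stats::rnorm(sum(post_sw), 0, config$resistance_cv))
  }
  attr(tr, "seed") <- config$seed
  tr
}

#' Synthetic stepped-osmolarity resistance plateaus
#'
#' Steady normalised structural resistances at a list of CPA-free
#' perfusate osmolarities, from the equilibrium volume, the volume-radius
#' relation and the fourth-power resistance law, with multiplicative
#' noise.
#'
#' @param config A [synth_config()].
#' @param osmolarities Perfusate osmolarities, mol/m^3 (>= 2 values).
#' @return A [bvh_dataset()] with the seed attached.
#' @export
gen_bvh_plateaus <- function(config = synth_config(),
                             osmolarities = c(283, 433, 583)) {
  if (length(osmolarities) < 2)
    stop("need at least 2 osmolarities")
  R <- steady_state_resistance(osmolarities, config$geometry, config$M_iso)
  if (config$resistance_cv > 0) {
    set.seed(config$seed)
    R <- R * (1 + stats::rnorm(length(R), 0, config$resistance_cv))
  }
  d <- bvh_dataset(osmolarities, R, M_iso = config$M_iso)
  attr(d, "seed") <- config$seed
  d
}

#' Synthetic slice-viability table
#'
#' Exponential-decay viability surface
#' \eqn{\exp(-\beta C^\alpha t)(1 + \epsilon)},
#' \eqn{\epsilon \sim N(0, sd)}, over a concentration x
#' exposure-time x replicate design, noise clipped at zero. The default
#' design mirrors the slice assay: C = 2.1, 4.2, 6.3, 8.4 M; t = 15, 30,
#' 45, 60, 90, 120 min; 4 replicates.
#'
#' @param config A [synth_config()].
#' @param concentrations Exposure concentrations, M.
#' @param times Exposure durations, min.
#' @param replicates Number of replicates per cell.
#' @return A [slice_dataset()] with the seed attached.
#' @export
gen_slice_viability <- function(config = synth_config(),
                                concentrations = c(2.1, 4.2, 6.3, 8.4),
                                times = c(15, 30, 45, 60, 90, 120),
                                replicates = 4) {
  g <- expand.grid(concentration_M = concentrations, time_min = times,
                   replicate = seq_len(replicates), KEEP.OUT.ATTRS = FALSE)
  v <- exp(-toxicity_rate(g$concentration_M, config$toxicity) * g$time_min)
  if (config$viability_sd > 0) {
    set.seed(config$seed)
    v <- pmax(v * (1 + stats::rnorm(nrow(g), 0, config$viability_sd)), 0)
  }
  d <- slice_dataset(g$concentration_M, g$time_min, g$replicate, v)
  attr(d, "seed") <- config$seed
  d
}
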