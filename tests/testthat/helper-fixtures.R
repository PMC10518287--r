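# shared fixtures: reference geometry/parameters and fast solver settings
ref_geom <- krogh_geometry()
ref_mem <- membrane_params()
ref_tox <- toxicity_params()
fast_settings <- sim_settings(output_dt = 5)

# a bare simulation-shaped object for constraint checks
fake_sim <- function(time_min, V_frac, baseline = 1) {
  structure(data.frame(time_min = time_min, V_frac = V_frac),
            baseline_V_frac = baseline)
}
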