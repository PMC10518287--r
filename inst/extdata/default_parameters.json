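{"r_c0_m":3e-06,"r_k_m":7.5e-06,"l_c_m":5.5e-05,"r_a_m":3.86e-06,"Lp_m3_per_N_s":1.5e-14,"omega_mol_per_N_s":7e-13,"sigma":0.1,"alpha":3.12,"beta_per_min_Malpha":9.39e-06,"temperature_K":277.15,"M_iso_mol_m3":290,"notes":"rat-kidney reference values: geometry from capillary morphometry; r_a, L_p, omega, sigma from perfusion fits; alpha, beta from slice toxicity calibration at 4C"}
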