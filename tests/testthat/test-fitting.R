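noiseless_cfg <- function(mem = ref_mem)
  synth_config(membrane = mem, resistance_cv = 0)

test_that("r_squared has its defining fixed points", {
  obs <- c(1, 0.9, 0.8, 0.85, 0.95)
  expect_equal(r_squared(obs, obs), 1)
  expect_equal(r_squared(obs, rep(mean(obs), 5)), 0)
  expect_error(r_squared(rep(1, 5), rep(1, 5)), "zero variance")
  expect_error(r_squared(1:2, 1:2))
})

test_that("L_p round-trips through a noiseless impermeant challenge", {
  tr <- gen_resistance_trace(noiseless_cfg(), "impermeant")
  fit <- fit_Lp(tr, ref_geom)
  expect_equal(fit$estimates$L_p, 1.5e-14, tolerance = 5e-3)
  expect_gt(fit$r_squared, 0.9999)
  expect_length(fit$bounds_hit, 0)
})

test_that("L_p recovery survives 2% multiplicative noise", {
  tr <- gen_resistance_trace(synth_config(seed = 7), "impermeant")
  fit <- fit_Lp(tr, ref_geom)
  expect_equal(fit$estimates$L_p, 1.5e-14, tolerance = 0.10)
  expect_gt(fit$r_squared, 0.95)
})

test_that("L_p estimate is stable under 2x subsampling", {
  tr <- gen_resistance_trace(noiseless_cfg(), "impermeant")
  full <- fit_Lp(tr, ref_geom)$estimates$L_p
  idx <- seq(1, nrow(tr), by = 2)
  half <- perfusion_trace(tr$time_min[idx], tr$Rp_norm[idx],
                          pre = attr(tr, "pre"), post = attr(tr, "post"))
  expect_equal(fit_Lp(half, ref_geom)$estimates$L_p, full,
               tolerance = 0.01)
})

test_that("flat traces are rejected as uninformative", {
  t <- seq(0, 15, by = 0.25)
  tr <- perfusion_trace(t, rep(1, length(t)))
  expect_error(fit_Lp(tr, ref_geom), "uninformative")
})

test_that("omega and sigma round-trip through a noiseless CPA challenge", {
  tr <- gen_resistance_trace(noiseless_cfg(), "cpa")
  fit <- fit_omega_sigma(tr, Lp = 1.5e-14, geom = ref_geom)
  expect_equal(fit$estimates$omega, 7.0e-13, tolerance = 0.01)
  expect_equal(fit$estimates$sigma, 0.10, tolerance = 0.01)
  expect_gt(fit$r_squared, 0.9999)
})

test_that("a freely permeating CPA produces no overshoot and is flagged", {
  # sigma = 0 removes the CPA osmotic term from J_v entirely: the tissue
  # volume never moves, the structural resistance stays flat, and omega
  # leaves no imprint on the trace. The fit must flag this rather than
  # report a confident estimate.
  mem0 <- membrane_params(sigma = 0)
  tr <- gen_resistance_trace(noiseless_cfg(mem0), "cpa",
                             viscosity_ratio = 1.3)
  post <- tr$Rp_norm[tr$time_min >= 0] / 1.3
  expect_lt(max(post) - min(post), 1e-6)   # no shrink-swell transient
  fit <- fit_omega_sigma(tr, Lp = 1.5e-14, geom = ref_geom)
  expect_true("non_identifiable_monotone" %in% fit$bounds_hit)
})

test_that("omega/sigma recovery survives 2% noise", {
  tr <- gen_resistance_trace(synth_config(seed = 11), "cpa")
  fit <- fit_omega_sigma(tr, Lp = 1.5e-14, geom = ref_geom)
  expect_equal(fit$estimates$omega, 7.0e-13, tolerance = 0.15)
  expect_lt(abs(fit$estimates$sigma - 0.10), 0.05)
})

test_that("random membrane parameters round-trip noiselessly", {
  # oracle is the forward model itself: generate -> fit -> compare
  set.seed(101)
  n_draw <- 8
  Lp_true <- 10^stats::runif(n_draw, -15, -13.2)
  om_true <- 10^stats::runif(n_draw, -13, -11.8)
  sg_true <- stats::runif(n_draw, 0.05, 0.5)
  for (i in seq_len(n_draw)) {
    mem <- membrane_params(Lp_true[i], om_true[i], sg_true[i])
    cfg <- noiseless_cfg(mem)
    fl <- fit_Lp(gen_resistance_trace(cfg, "impermeant"), ref_geom)
    expect_equal(fl$estimates$L_p, Lp_true[i], tolerance = 0.01)
    fo <- fit_omega_sigma(gen_resistance_trace(cfg, "cpa"),
                          Lp = Lp_true[i], geom = ref_geom)
    expect_equal(fo$estimates$omega, om_true[i], tolerance = 0.01)
    expect_equal(fo$estimates$sigma, sg_true[i], tolerance = 0.01)
  }
})

test_that("the generating parameters sit at a residual minimum", {
  tr <- gen_resistance_trace(noiseless_cfg(), "cpa")
  y <- tr$Rp_norm[tr$time_min >= 0]
  ssr <- function(om, sg) {
    mem <- membrane_params(1.5e-14, om, sg)
    sim <- simulate_switch(attr(tr, "pre"), attr(tr, "post"),
                           duration_min = 30, geom = ref_geom, mem = mem,
                           baseline_min = 0, sample_dt = 0.25)
    sum((sim$Rp_norm - y)^2)
  }
  s0 <- ssr(7.0e-13, 0.10)
  for (f in c(0.9, 1.1)) {
    expect_gt(ssr(7.0e-13 * f, 0.10), s0)
    expect_gt(ssr(7.0e-13, 0.10 * f), s0)
  }
})

test_that("challenge type is validated against the trace metadata", {
  tr_cpa <- gen_resistance_trace(noiseless_cfg(), "cpa")
  expect_error(fit_Lp(tr_cpa, ref_geom), "CPA-free")
  tr_imp <- gen_resistance_trace(noiseless_cfg(), "impermeant")
  expect_error(fit_omega_sigma(tr_imp, Lp = 1.5e-14, geom = ref_geom),
               "CPA-bearing")
})
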