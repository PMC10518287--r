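test_that("protocol construction computes the plateau and validates it", {
  p <- build_protocol(50, 100, 10, full_strength_duration = 25)
  expect_equal(p$plateau_conc, 5.0)
  expect_equal(p$ramp_duration + p$plateau_duration, 110)
  expect_equal(build_protocol(62, 80, 5)$plateau_conc, 4.96)
  expect_error(build_protocol(90, 120, 5), "exceeds full strength")
  # flush-only protocol carries no CPA at any time
  p0 <- build_protocol(0, 0, 0, full_strength_conc = 0,
                       full_strength_duration = 0)
  expect_true(all(arterial_concentration(p0, c(-10, 0, 5, 50)) == 0))
})

test_that("arterial schedule reproduces the ramp-hold-step shape", {
  p <- existing_protocol()
  expect_equal(arterial_concentration(p, c(-5, 0, 50, 100, 105, 120)),
               c(0, 0, 2.5, 5, 5, 8.4))
  expect_equal(arterial_pressure(p, c(50, 109, 111)), c(40, 40, 60))
})

test_that("osmotic feasibility follows the floors and the stress budget", {
  cons <- osmotic_constraints()
  t <- seq(0, 100, by = 1)
  ok <- check_osmotic(fake_sim(t, rep(1, length(t))), cons)
  expect_true(ok$feasible)
  expect_equal(ok$min_Vfrac, 1)
  expect_equal(ok$time_below_stress_floor, 0)
  # dip below the hard floor
  v <- rep(1, length(t)); v[40:45] <- 0.40
  expect_false(check_osmotic(fake_sim(t, v), cons)$feasible)
  # long soft-stress excursion: 0.70 for 30 min
  v2 <- rep(1, length(t)); v2[31:61] <- 0.70
  chk <- check_osmotic(fake_sim(t, v2), cons)
  expect_false(chk$feasible)
  expect_equal(chk$min_Vfrac, 0.70)
  expect_gte(chk$time_below_stress_floor, 29)
  # the same excursion split into two 15-min halves passes in contiguous
  # mode but fails the cumulative budget
  v3 <- rep(1, length(t)); v3[11:26] <- 0.70; v3[61:76] <- 0.70
  expect_false(check_osmotic(fake_sim(t, v3), cons)$feasible)
  cons2 <- osmotic_constraints(stress_mode = "contiguous")
  expect_true(check_osmotic(fake_sim(t, v3), cons2)$feasible)
})

test_that("volume floors are taken relative to the flush baseline", {
  t <- seq(0, 10, 1)
  # V_frac 0.80 of V0 against a baseline of 0.879 is 0.91 of baseline
  chk <- check_osmotic(fake_sim(t, rep(0.80, length(t)), baseline = 0.879))
  expect_equal(chk$min_Vfrac, 0.80 / 0.879, tolerance = 1e-6)
  expect_true(chk$feasible)
})

test_that("a single-point grid reproduces the plain simulation", {
  g <- optimization_grid(ramp_rate = 50, ramp_duration = 100,
                         plateau_duration = 10)
  # fixed 25-min hold via a target chosen as that simulation's endpoint
  ref <- simulate_loading(existing_protocol(), ref_geom, ref_mem, ref_tox,
                          fast_settings)
  opt <- optimize_protocol(g, ref_geom, ref_mem, ref_tox, fast_settings)
  expect_equal(opt$best$ramp_rate, 50)
  expect_equal(opt$best$J_tox, attr(ref, "J_tox"), tolerance = 5e-3)
  expect_equal(opt$best$full_strength_min, 25, tolerance = 0.05)
  expect_equal(opt$target_conc, attr(ref, "C_end"))
})

small_grid <- optimization_grid(ramp_rate = seq(50, 70, by = 10),
                                ramp_duration = seq(80, 120, by = 20),
                                plateau_duration = c(4, 10))

test_that("the grid search is deterministic and reports feasible argmins", {
  o1 <- optimize_protocol(small_grid, ref_geom, ref_mem, ref_tox,
                          fast_settings)
  o2 <- optimize_protocol(small_grid, ref_geom, ref_mem, ref_tox,
                          fast_settings)
  expect_identical(o1$records, o2$records)
  expect_identical(o1$per_rate, o2$per_rate)
  b <- o1$best
  expect_true(b$feasible)
  expect_gte(b$plateau_conc, 3)
  expect_lte(b$plateau_conc, 7)
  expect_gte(b$min_Vfrac, 0.45)
  expect_lte(b$time_below, 25)
  # every feasible record satisfies the constraints it was screened by
  feas <- o1$records[o1$records$feasible, ]
  expect_true(all(feas$min_Vfrac >= 0.45))
  expect_true(all(feas$time_below <= 25))
})

test_that("refining the grid never raises the minimum toxicity", {
  coarse <- optimization_grid(ramp_rate = c(50, 60, 70),
                              ramp_duration = c(80, 120),
                              plateau_duration = c(4, 12))
  fine <- optimization_grid(ramp_rate = c(50, 55, 60, 65, 70),
                            ramp_duration = c(80, 100, 120),
                            plateau_duration = c(4, 8, 12))
  oc <- optimize_protocol(coarse, ref_geom, ref_mem, ref_tox, fast_settings)
  of <- optimize_protocol(fine, ref_geom, ref_mem, ref_tox, fast_settings)
  expect_lte(of$best$J_tox, oc$best$J_tox + 1e-12)
})

test_that("an unreachable target empties the feasible set", {
  g <- optimization_grid(ramp_rate = 50, ramp_duration = 80,
                         plateau_duration = 4)
  expect_error(optimize_protocol(g, ref_geom, ref_mem, ref_tox,
                                 fast_settings, target_conc = 8.4,
                                 max_full_strength = 10),
               "no feasible protocol")
})

test_that("an immediately satisfied target gives a zero-length hold", {
  hold <- auto_full_strength_duration(build_protocol(50, 100, 10), 2.0,
                                      ref_geom, ref_mem, ref_tox,
                                      fast_settings)
  expect_lt(hold, 0.2)
})
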