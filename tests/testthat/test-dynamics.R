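test_that("acceleration vanishes at static equilibrium and drives collapse at the apex", {
  amb <- ambient_conditions()
  mat <- material(elastic_modulus = 20e3, surface_tension = 0)
  geom <- cycle_geometry(120e-6, mat, amb)
  # at R_0 with zero velocity: gas balances far field, elastic stress zero
  expect_equal(bubble_acceleration(geom$R_0, 0, "elastic_growth", mat, amb,
                                   geom), 0, tolerance = 1e-6)
  # at the apex of an inviscid, tension-free, stress-free bubble only the
  # pressure deficit survives: (p_v - p_inf) / (rho R_max)
  mat0 <- inviscid_water()
  geom0 <- cycle_geometry(120e-6, mat0, amb)
  expect_equal(bubble_acceleration(120e-6, 0, "elastic_growth", mat0, amb,
                                   geom0),
               (3169 - 101325) / (997 * 120e-6))
  expect_lt(bubble_acceleration(120e-6, 0, "elastic_growth", mat0, amb,
                                geom0), 0)
  # zero modulus makes the elastic phase identical to the Newtonian one
  for (R in c(60e-6, 90e-6, 119e-6)) {
    expect_equal(bubble_acceleration(R, 5, "elastic_growth", mat0, amb, geom0),
                 bubble_acceleration(R, 5, "newtonian", mat0, amb, geom0))
  }
  expect_error(bubble_acceleration(-1e-6, 0, "newtonian", mat0, amb, geom0),
               "radius")
})

test_that("inviscid tension-free cycle matches the Rayleigh closed form within 2%", {
  tr <- simulate_cycle(120e-6, inviscid_water(), mode = "newtonian")
  expect_equal(cycle_time_ratio(tr), 1, tolerance = 0.02)
})

test_that("trajectory peaks at R_max, is unimodal, with strictly increasing time", {
  for (mode in c("failure", "elastic", "newtonian")) {
    tr <- simulate_cycle(126e-6, fibrin_like(), mode = mode)
    s <- tr$states
    expect_true(all(diff(s$time) > 0))
    expect_equal(max(s$radius), 126e-6, tolerance = 1e-3)
    # unimodal: radius rises to the peak then falls
    peak <- which.max(s$radius)
    expect_true(all(diff(s$radius[1:peak]) >= 0))
    expect_true(all(diff(s$radius[peak:nrow(s)]) <= 0))
  }
})

test_that("phases are ordered elastic -> plastic -> recovery with continuous stress", {
  tr <- simulate_cycle(126e-6, fibrin_like())
  expect_true(tr$failed)
  s <- tr$states
  first <- tapply(s$time, s$phase, min)
  expect_lt(first[["elastic_growth"]], first[["plastic_growth"]])
  expect_lt(first[["plastic_growth"]], first[["recovery"]])
  # plastic phase only before the apex
  apex_t <- tr$T_growth
  expect_true(all(s$time[s$phase %in% c("elastic_growth", "plastic_growth")]
                  <= apex_t + 1e-12))
  # stress continuity across the two switch points
  g <- tr$geometry
  eta <- 20e3
  expect_equal(elastic_stress_intact(g$R_f, g$R_0, eta), g$E_f)
  expect_equal(elastic_stress_recovery(g$R_max, g$R_0, g$R_max, g$E_f),
               g$E_f)
})

test_that("growth and collapse are time mirrors for a lossless intact cycle", {
  mat <- material(elastic_modulus = 15e3, kinematic_viscosity = 0,
                  surface_tension = 0)
  tr <- simulate_cycle(110e-6, mat, mode = "elastic")
  expect_equal(tr$T_growth, tr$T_collapse, tolerance = 1e-6)
})

test_that("zero failure strain and no-failure sentinel reduce to the expected limits", {
  # eps_f = 0: plateau and recovery stresses vanish, so the cycle matches a
  # zero-modulus material
  tr0 <- simulate_cycle(120e-6, fibrin_like(eta = 30e3, eps = 0))
  trw <- simulate_cycle(120e-6, material())
  expect_equal(tr0$T_hg, trw$T_hg, tolerance = 1e-3)
  # eps_f >= 0.5 behaves exactly as the no-failure elastic mode
  tr1 <- simulate_cycle(120e-6, fibrin_like(eta = 30e3, eps = 0.6))
  tr2 <- simulate_cycle(120e-6, fibrin_like(eta = 30e3, eps = 0.2),
                        mode = "elastic")
  expect_false(tr1$failed)
  expect_equal(tr1$T_hg, tr2$T_hg, tolerance = 1e-9)
})

test_that("adaptive solver agrees with an independent fixed-step RK4 oracle", {
  set.seed(42)
  for (i in 1:5) {
    R_max <- runif(1, 70, 150) * 1e-6
    mat <- fibrin_like(eta = runif(1, 5, 45) * 1e3,
                       eps = runif(1, 0.05, 0.45))
    tr <- simulate_cycle(R_max, mat)
    oracle <- rk4_cycle_time(R_max, mat)
    expect_equal(tr$T_hg, oracle, tolerance = 1e-3)
  }
})

test_that("water-limit cycle time follows the Rayleigh formula", {
  expect_equal(water_cycle_time(124e-6),
               2 * 0.915 * 124e-6 * sqrt(997 / (101325 - 3169)))
  expect_equal(water_cycle_time(0), 0)
  expect_equal(water_cycle_time(2 * 68e-6), 2 * water_cycle_time(68e-6))
})

test_that("simulation rejects invalid maximum radii", {
  expect_error(simulate_cycle(0, material()), "positive")
  expect_error(simulate_cycle(-1e-6, material()), "positive")
})

test_that("sensitivity map is doubly monotone with its corner minimum", {
  fast <- solver_options(rtol = 1e-7, n_out = 60)
  map <- sensitivity_map(120e-6, eta_grid = c(0, 20e3, 40e3),
                         eps_grid = c(0, 0.25, 0.5), solver = fast)
  expect_equal(nrow(map), 9L)
  # eta = 0 row: no elasticity regardless of failure strain
  r0 <- map$ratio[map$elastic_modulus == 0]
  expect_lt(max(abs(r0 - r0[1])), 1e-6)
  # decreasing along eta at positive eps, and along eps at positive eta
  for (ef in c(0.25, 0.5)) {
    col <- map$ratio[map$radial_failure_strain == ef]
    expect_true(all(diff(col) < 0))
  }
  for (eta in c(20e3, 40e3)) {
    row <- map$ratio[map$elastic_modulus == eta]
    expect_true(all(diff(row) < 0))
  }
  expect_equal(which.min(map$ratio),
               which(map$elastic_modulus == 40e3 &
                       map$radial_failure_strain == 0.5))
})
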