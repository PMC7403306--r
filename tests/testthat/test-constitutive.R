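test_that("equilibrium radius follows the adiabatic balance and scales with R_max", {
  amb <- ambient_conditions()
  # closed form: R0 = Rmax * (pv/pinf)^(1/(3 kappa))
  expect_equal(equilibrium_radius(70e-6, amb),
               70e-6 * (3169 / 101325) ^ 0.25)
  # scale equivariance and monotonicity
  expect_equal(equilibrium_radius(2 * 70e-6, amb),
               2 * equilibrium_radius(70e-6, amb))
  r <- equilibrium_radius(c(50, 100, 150) * 1e-6, amb)
  expect_true(all(diff(r) > 0))
  expect_error(equilibrium_radius(-1e-6, amb), "positive")
})

test_that("internal pressure obeys the gas law at its anchor points", {
  amb <- ambient_conditions()
  R <- 100e-6
  expect_equal(internal_pressure(R, R, amb), 3169)
  # R = Rmax/2 with kappa = 4/3: factor 2^4
  expect_equal(internal_pressure(R / 2, R, amb), 16 * 3169)
  # at the equilibrium radius the gas pressure balances the far field
  expect_equal(internal_pressure(equilibrium_radius(R, amb), R, amb),
               101325, tolerance = 1e-12)
  expect_error(internal_pressure(0, R, amb), "> 0")
})

test_that("intact elastic stress has the Neo-Hookean shape", {
  R0 <- 40e-6
  expect_equal(elastic_stress_intact(R0, R0, 20e3), 0)
  # R0/R = 0.5: (eta/2)(5 - 2 - 1/16)
  expect_equal(elastic_stress_intact(2 * R0, R0, 20e3), 29375)
  # large-radius asymptote 5 eta / 2
  expect_equal(elastic_stress_intact(1e6 * R0, R0, 20e3), 50e3,
               tolerance = 1e-5)
  # compressed below equilibrium the stress is negative
  expect_lt(elastic_stress_intact(0.5 * R0, R0, 20e3), 0)
})

test_that("failure and recovery stresses join the intact law continuously", {
  R0 <- 40e-6
  Rf <- failure_radius(0.25, R0)
  expect_equal(Rf, R0 * 0.5 ^ (-0.25))
  Ef <- failure_stress(Rf, R0, 20e3)
  # hand value: 10 kPa * (5 - 4/1.1892 - 0.5)
  expect_equal(Ef, 1e4 * (5 - 4 / 0.5 ^ (-0.25) - 0.5), tolerance = 1e-12)
  expect_equal(failure_stress(R0, R0, 20e3), 0)
  expect_equal(failure_stress(Rf, R0, 0), 0)
  expect_error(failure_stress(0.9 * R0, R0, 20e3), ">= R_0")
  # recovery path: equals E_f at the apex, zero at equilibrium
  Rmax <- 120e-6
  expect_equal(elastic_stress_recovery(Rmax, R0, Rmax, Ef), Ef)
  expect_equal(elastic_stress_recovery(R0, R0, Rmax, Ef), 0)
  expect_equal(elastic_stress_recovery(70e-6, R0, Rmax, 0), 0)
  expect_error(elastic_stress_recovery(70e-6, R0, R0, Ef), "degenerate")
})

test_that("stress laws are homogeneous of degree one in the modulus", {
  R0 <- 40e-6
  Rf <- failure_radius(0.3, R0)
  for (R in c(30e-6, 60e-6, 110e-6)) {
    expect_equal(elastic_stress_intact(R, R0, 42e3),
                 2.1 * elastic_stress_intact(R, R0, 20e3))
    Ef1 <- failure_stress(Rf, R0, 20e3)
    expect_equal(elastic_stress_recovery(R, R0, 120e-6, 2.1 * Ef1),
                 2.1 * elastic_stress_recovery(R, R0, 120e-6, Ef1))
  }
})

test_that("wall strains match the Green-Lagrange forms and bounds", {
  R0 <- 40e-6
  s <- wall_strains(R0, R0)
  expect_equal(s$radial, 0)
  expect_equal(s$circumferential, 0)
  s2 <- wall_strains(2 * R0, R0)
  expect_equal(s2$radial, 0.5 * (1 - 1 / 16))
  expect_equal(s2$circumferential, 1.5)
  # radial strain asymptote 0.5
  expect_lt(wall_strains(1e3 * R0, R0)$radial, 0.5)
  expect_equal(wall_strains(1e6 * R0, R0)$radial, 0.5, tolerance = 1e-12)
})

test_that("failure radius inverts the radial wall strain (round trip)", {
  R0 <- 37e-6
  expect_equal(failure_radius(0, R0), R0)
  expect_equal(failure_radius(0.46875, R0), 2 * R0)
  for (eps in seq(0, 0.49, by = 0.07)) {
    Rf <- failure_radius(eps, R0)
    expect_equal(wall_strains(Rf, R0)$radial, eps, tolerance = 1e-14)
  }
  expect_identical(failure_radius(0.5, R0), Inf)
  expect_identical(failure_radius(0.7, R0), Inf)
  expect_error(failure_radius(-0.1, R0), ">= 0")
})

test_that("circumferential failure strain composes the wall relations", {
  expect_equal(circumferential_failure_strain(0), 0)
  expect_equal(circumferential_failure_strain(0.25),
               0.5 * (0.5 ^ (-0.5) - 1))
  # equals the circumferential wall strain evaluated at the failure radius
  R0 <- 52e-6
  for (eps in c(0.1, 0.23, 0.37, 0.45)) {
    expect_equal(circumferential_failure_strain(eps),
                 wall_strains(failure_radius(eps, R0), R0)$circumferential)
  }
  e <- circumferential_failure_strain(seq(0, 0.45, by = 0.05))
  expect_true(all(diff(e) > 0))
  expect_identical(circumferential_failure_strain(0.5), Inf)
})

test_that("material constructor normalizes the no-failure flag and validates", {
  expect_identical(material(radial_failure_strain = 0.5)$radial_failure_strain,
                   Inf)
  expect_identical(material(radial_failure_strain = 2)$radial_failure_strain,
                   Inf)
  expect_equal(material(radial_failure_strain = 0.3)$radial_failure_strain,
               0.3)
  expect_error(material(density = 0), "density")
  expect_error(material(elastic_modulus = -1), "elastic_modulus")
  expect_error(ambient_conditions(vapor_pressure = 2e5), "vapor_pressure")
  expect_error(ambient_conditions(adiabatic_index = 1), "adiabatic_index")
})

test_that("cycle geometry flags failure only when the cycle reaches R_f", {
  g <- cycle_geometry(126e-6, fibrin_like())
  expect_true(g$failed)
  expect_gt(g$R_f, g$R_0)
  expect_lt(g$R_f, g$R_max)
  # a failure strain requiring a radius beyond R_max: material stays intact
  g2 <- cycle_geometry(50e-6, fibrin_like(eps = 0.49))
  expect_false(g2$failed)
  g3 <- cycle_geometry(126e-6, material())
  expect_false(g3$failed)
  expect_identical(g3$R_f, Inf)
})
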