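#' Solver options for the cycle integrator
#'
#' @param rtol Relative tolerance of the adaptive integrator.
#' @param atol_radius Absolute tolerance on the radius (m).
#' @param atol_velocity Absolute tolerance on the wall velocity (m/s).
#' @param max_step_frac Maximum internal step as a fraction of the analytic
#'   water cycle time; keeps the step bounded through the stiff small-radius
#'   endgame where the gas term grows as R^-4.
#' @param n_out Number of output samples requested per integration leg.
#' @return A list of class `lcr_solver_options`.
#' @export
solver_options <- function(rtol = 1e-9, atol_radius = 1e-13,
                           atol_velocity = 1e-7, max_step_frac = 0.005,
                           n_out = 400) {
  stopifnot(rtol > 0, atol_radius > 0, atol_velocity > 0,
            max_step_frac > 0, n_out >= 10)
  structure(list(rtol = rtol, atol_radius = atol_radius,
                 atol_velocity = atol_velocity,
                 max_step_frac = max_step_frac, n_out = n_out),
            class = "lcr_solver_options")
}

#' Analytic water-limit cycle time
#'
#' Twice the Rayleigh collapse time of an empty cavity in an inviscid liquid:
#' `T_w = 2 * 0.915 * R_max * sqrt(rho / (p_inf - p_v))`. Used as the
#' elasticity-free reference against which hydrogel cycle times are compared.
#'
#' @param R_max Maximum bubble radius (m). Vectorized.
#' @param density Liquid density (kg/m^3).
#' @param ambient [ambient_conditions()].
#' @return Cycle time (s).
#' @examples
#' water_cycle_time(124e-6) * 1e6  # ~22.9 us
#' @export
water_cycle_time <- function(R_max, density = 997,
                             ambient = ambient_conditions()) {
  if (any(R_max < 0)) stop("R_max must be >= 0")
  2 * 0.915 * R_max *
    sqrt(density / (ambient$far_field_pressure - ambient$vapor_pressure))
}

# Elastic stress by phase. Phases: "elastic_growth" (intact law),
# "plastic_growth" (plateau), "recovery" (rescaled law), "newtonian" (zero).
phase_stress <- function(radius, phase, mat, geom) {
  switch(phase,
         elastic_growth = ,
         elastic = elastic_stress_intact(radius, geom$R_0, mat$elastic_modulus),
         plastic_growth = geom$E_f,
         recovery = elastic_stress_recovery(radius, geom$R_0, geom$R_max,
                                            geom$E_f),
         newtonian = 0,
         stop("unknown phase: ", phase))
}

#' Radial acceleration of the bubble wall
#'
#' Right-hand side of the governing equation
#' `R R'' + 3/2 R'^2 = (p_B - p_inf)/rho - 2S/(rho R) - 4 nu R'/R - E/rho`
#' solved for `R''`, with the elastic stress `E` selected by the deformation
#' phase: intact Neo-Hookean during elastic growth (and throughout a
#' no-failure cycle), the constant plateau stress during plastic growth, the
#' rescaled recovery law during post-failure collapse, and zero for a
#' Newtonian fluid.
#'
#' @param radius Bubble radius (m), > 0.
#' @param velocity Wall velocity dR/dt (m/s).
#' @param phase One of `"elastic_growth"`, `"plastic_growth"`, `"recovery"`,
#'   `"elastic"`, `"newtonian"`.
#' @param mat [material()].
#' @param ambient [ambient_conditions()].
#' @param geom [cycle_geometry()] for the cycle being integrated.
#' @return Acceleration d2R/dt2 (m/s^2).
#' @export
bubble_acceleration <- function(radius, velocity, phase, mat,
                                ambient = ambient_conditions(),
                                geom = cycle_geometry(radius, mat, ambient)) {
  if (any(radius <= 0)) stop("radius must be > 0 inside the integration domain")
  E <- phase_stress(radius, phase, mat, geom)
  p_B <- internal_pressure(radius, geom$R_max, ambient)
  rho <- mat$density
  ((p_B - ambient$far_field_pressure) / rho -
     2 * mat$surface_tension / (rho * radius) -
     4 * mat$kinematic_viscosity * velocity / radius -
     E / rho - 1.5 * velocity ^ 2) / radius
}

# One integration leg away from the apex (R_max, V = 0). Reversed legs solve
# the time-mirrored equation (velocity sign flipped in the viscous term).
# Starts a small analytic series step from the apex so the velocity-zero root
# does not fire at t = 0; terminates on `rootfun`.
integrate_leg <- function(y0, rhs, rootfun, t0, t_max, solver, hmax) {
  times <- seq(t0, t_max, length.out = solver$n_out)
  out <- deSolve::lsodar(y = y0, times = times, func = rhs, parms = NULL,
                         rootfunc = rootfun, rtol = solver$rtol,
                         atol = c(solver$atol_radius, solver$atol_velocity),
                         hmax = hmax)
  if (is.null(attr(out, "troot")))
    stop(sprintf(paste0("cycle solver found no terminating event in ",
                        "[%.3g, %.3g] s (final radius %.3g m, velocity ",
                        "%.3g m/s); check material/ambient parameters"),
                 t0, t_max, out[nrow(out), 2], out[nrow(out), 3]))
  out
}

apex_start <- function(rhs, R_max, eps) {
  a0 <- rhs(0, c(R_max, 0), NULL)[[1]][2]
  c(R_max + 0.5 * a0 * eps ^ 2, a0 * eps)
}

#' Simulate one full cavitation bubble cycle
#'
#' Integrates the governing equation through a complete growth/collapse cycle
#' with the phase-switched constitutive law. The growth phase is obtained by
#' time-reversed integration from the apex `(R_max, dR/dt = 0)` — applying
#' the plastic plateau for radii in `[R_f, R_max]` when failure occurs and
#' the intact law below — until the reversed trajectory reaches a velocity
#' turning point at small radius; the collapse phase is integrated forward
#' from the apex under the recovery law (intact law for a no-failure cycle,
#' zero stress for a Newtonian fluid) until the rebound turning point. The
#' two halves are concatenated with `t = 0` at the growth-side turning point.
#'
#' Starting at the apex guarantees the simulated peak equals the `R_max`
#' parameter that also fixes the gas law, and avoids shooting for the peak
#' against viscous losses.
#'
#' @param R_max Maximum bubble radius (m).
#' @param mat [material()].
#' @param ambient [ambient_conditions()].
#' @param mode `"failure"` (phase-switched law; reduces to the intact law
#'   when the material cannot fail within the cycle), `"elastic"` (intact law
#'   throughout, ignoring any failure strain), or `"newtonian"` (no elastic
#'   stress).
#' @param solver [solver_options()].
#' @return An object of class `lcr_trajectory`: a list with `states` (a
#'   data.frame `time`, `radius`, `velocity`, `phase`), `geometry`, `T_hg`
#'   (turning point to turning point, s), `T_growth`, `T_collapse`, `failed`,
#'   `mode`, `material`, `ambient`.
#' @examples
#' traj <- simulate_cycle(126e-6, material(20e3, radial_failure_strain = 0.25))
#' traj$T_hg * 1e6
#' @export
simulate_cycle <- function(R_max, mat = material(),
                           ambient = ambient_conditions(),
                           mode = c("failure", "elastic", "newtonian"),
                           solver = solver_options()) {
  mode <- match.arg(mode)
  geom <- cycle_geometry(R_max, mat, ambient)
  if (R_max <= geom$R_0)
    stop("R_max must exceed the equilibrium radius")
  if (mode != "failure") geom$failed <- FALSE
  failed <- mode == "failure" && geom$failed

  Tw <- water_cycle_time(R_max, mat$density, ambient)
  hmax <- Tw * solver$max_step_frac
  eps <- 1e-6 * Tw
  t_max <- 2.5 * Tw

  growth_law <- if (mode == "newtonian") "newtonian" else "elastic_growth"
  collapse_law <- if (mode == "newtonian") "newtonian"
                  else if (failed) "recovery" else "elastic"

  rhs_rev <- function(law) function(t, y, p) {
    a <- bubble_acceleration(y[1], -y[2], law, mat, ambient, geom)
    list(c(y[2], a))
  }
  rhs_fwd <- function(law) function(t, y, p) {
    a <- bubble_acceleration(y[1], y[2], law, mat, ambient, geom)
    list(c(y[2], a))
  }
  root_v <- function(t, y, p) y[2]
  root_rf <- function(t, y, p) y[1] - geom$R_f

  # growth, integrated in reversed time from the apex
  if (failed) {
    y0 <- apex_start(rhs_rev("plastic_growth"), R_max, eps)
    leg1 <- integrate_leg(y0, rhs_rev("plastic_growth"), root_rf, eps, t_max,
                          solver, hmax)
    t1 <- leg1[nrow(leg1), 1]
    y1 <- as.numeric(leg1[nrow(leg1), 2:3])
    leg2 <- integrate_leg(y1, rhs_rev(growth_law), root_v, t1, t1 + t_max,
                          solver, hmax)
    growth <- rbind(leg1[-nrow(leg1), , drop = FALSE], leg2)
  } else {
    y0 <- apex_start(rhs_rev(growth_law), R_max, eps)
    growth <- integrate_leg(y0, rhs_rev(growth_law), root_v, eps, t_max,
                            solver, hmax)
  }
  T_growth <- unname(growth[nrow(growth), 1])

  # collapse, forward from the apex
  y0 <- apex_start(rhs_fwd(collapse_law), R_max, eps)
  collapse <- integrate_leg(y0, rhs_fwd(collapse_law), root_v, eps, t_max,
                            solver, hmax)
  T_collapse <- unname(collapse[nrow(collapse), 1])

  g_phase <- if (mode == "newtonian") rep("newtonian", nrow(growth))
             else if (failed) ifelse(growth[, 2] >= geom$R_f,
                                     "plastic_growth", "elastic_growth")
             else rep(if (mode == "elastic") "elastic" else "elastic_growth",
                      nrow(growth))
  states <- rbind(
    data.frame(time = T_growth - growth[, 1], radius = growth[, 2],
               velocity = -growth[, 3], phase = g_phase),
    data.frame(time = T_growth + collapse[, 1], radius = collapse[, 2],
               velocity = collapse[, 3], phase = collapse_law))
  states <- states[order(states$time), , drop = FALSE]
  states <- states[!duplicated(states$time), , drop = FALSE]
  rownames(states) <- NULL

  structure(list(states = states, geometry = geom,
                 T_hg = T_growth + T_collapse,
                 T_growth = T_growth, T_collapse = T_collapse,
                 failed = failed, mode = mode,
                 material = mat, ambient = ambient),
            class = "lcr_trajectory")
}

#' @export
print.lcr_trajectory <- function(x, ...) {
  cat("<lcr_trajectory>\n")
  cat(sprintf("  mode %s, R_max %.1f um, R_0 %.1f um, %s\n", x$mode,
              x$geometry$R_max * 1e6, x$geometry$R_0 * 1e6,
              if (x$failed) sprintf("failed at R_f %.1f um",
                                    x$geometry$R_f * 1e6)
              else "no failure"))
  cat(sprintf("  cycle time %.3f us (growth %.3f + collapse %.3f), %d states\n",
              x$T_hg * 1e6, x$T_growth * 1e6, x$T_collapse * 1e6,
              nrow(x$states)))
  invisible(x)
}

#' Interpolate the bubble radius at given times
#'
#' Cubic-spline interpolation of the simulated radius (the trajectory is
#' smooth between output samples, and the fit's parameter sensitivities are
#' far below linear-interpolation error); times outside the cycle window
#' `[0, T_hg]` return the radius at the nearest cycle endpoint (the
#' documented convention used by the fit residuals).
#'
#' @param trajectory An `lcr_trajectory`.
#' @param time Times since the growth-side turning point (s). Vectorized.
#' @return Radii (m).
#' @export
trajectory_radius <- function(trajectory, time) {
  s <- trajectory$states
  f <- stats::splinefun(s$time, s$radius, method = "fmm")
  f(pmin(pmax(time, s$time[1]), s$time[nrow(s)]))
}

#' Cycle-time ratio relative to water
#'
#' Ratio of the simulated hydrogel cycle time `T_hg` to the analytic
#' water-limit value for the same maximum radius. Elasticity shortens the
#' cycle, so the ratio drops below one as modulus or failure strain grow.
#'
#' @param trajectory An `lcr_trajectory`.
#' @param density Density used for the water reference (defaults to the
#'   trajectory material's density).
#' @return Dimensionless ratio `T_hg / T_w`.
#' @export
cycle_time_ratio <- function(trajectory, density = NULL) {
  if (is.null(density)) density <- trajectory$material$density
  trajectory$T_hg /
    water_cycle_time(trajectory$geometry$R_max, density, trajectory$ambient)
}

#' Cycle-shortening sensitivity map
#'
#' Simulates one full cycle per (elastic modulus, radial failure strain) grid
#' point at fixed maximum radius and tabulates the cycle time and its ratio
#' to water. The ratio decreases along both axes: a stiffer material and a
#' later-failing material both offer more elastic resistance.
#'
#' @param R_max Maximum bubble radius (m).
#' @param eta_grid Elastic moduli (Pa).
#' @param eps_grid Radial failure strains (values >= 0.5 mean no failure).
#' @param mat_base [material()] supplying viscosity, density and surface
#'   tension.
#' @param ambient [ambient_conditions()].
#' @param solver [solver_options()].
#' @return data.frame with columns `elastic_modulus`, `radial_failure_strain`,
#'   `T_hg`, `ratio`.
#' @export
sensitivity_map <- function(R_max = 120e-6,
                            eta_grid = seq(0, 40e3, by = 10e3),
                            eps_grid = seq(0, 0.5, by = 0.1),
                            mat_base = material(),
                            ambient = ambient_conditions(),
                            solver = solver_options()) {
  if (!length(eta_grid) || !length(eps_grid)) stop("grids must be non-empty")
  grid <- expand.grid(elastic_modulus = eta_grid,
                      radial_failure_strain = eps_grid)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    mat <- material(elastic_modulus = grid$elastic_modulus[i],
                    kinematic_viscosity = mat_base$kinematic_viscosity,
                    density = mat_base$density,
                    surface_tension = mat_base$surface_tension,
                    radial_failure_strain = grid$radial_failure_strain[i])
    tr <- tryCatch(simulate_cycle(R_max, mat, ambient, solver = solver),
                   error = function(e)
                     stop(sprintf("sensitivity_map failed at eta=%g, eps=%g: %s",
                                  grid$elastic_modulus[i],
                                  grid$radial_failure_strain[i],
                                  conditionMessage(e))))
    c(T_hg = tr$T_hg, ratio = cycle_time_ratio(tr))
  })
  cbind(grid, do.call(rbind, res))
}
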