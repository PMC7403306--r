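#' Mechanical constants of the surrounding medium
#'
#' Bundles the material parameters entering the bubble-dynamics model: the
#' Neo-Hookean elastic modulus, kinematic viscosity, density, surface tension
#' at the bubble wall, and the radial wall strain at which the material
#' ruptures. The radial wall strain is bounded above by 0.5 (its large-radius
#' asymptote), so any value >= 0.5 means the material never fails and is
#' stored as the explicit no-failure flag `Inf`.
#'
#' Defaults describe a water-like medium with no elasticity and no failure:
#' nu = 1e-6 m^2/s, rho = 997 kg/m^3, S = 0.072 N/m.
#'
#' @param elastic_modulus Elastic modulus (Pa), >= 0.
#' @param kinematic_viscosity Kinematic viscosity (m^2/s), >= 0.
#' @param density Density (kg/m^3), > 0.
#' @param surface_tension Surface tension (N/m), >= 0.
#' @param radial_failure_strain Radial wall strain at rupture (dimensionless,
#'   in `[0, 0.5)`); values >= 0.5 (including `Inf`) mean "never fails".
#' @return An object of class `lcr_material`.
#' @examples
#' fibrin <- material(elastic_modulus = 20e3, radial_failure_strain = 0.25)
#' water <- material()
#' @export
material <- function(elastic_modulus = 0,
                     kinematic_viscosity = 1e-6,
                     density = 997,
                     surface_tension = 0.072,
                     radial_failure_strain = Inf) {
  stopifnot(is.numeric(elastic_modulus), length(elastic_modulus) == 1L,
            is.numeric(kinematic_viscosity), length(kinematic_viscosity) == 1L,
            is.numeric(density), length(density) == 1L,
            is.numeric(surface_tension), length(surface_tension) == 1L,
            is.numeric(radial_failure_strain), length(radial_failure_strain) == 1L)
  if (elastic_modulus < 0) stop("elastic_modulus must be >= 0 Pa")
  if (kinematic_viscosity < 0) stop("kinematic_viscosity must be >= 0 m^2/s")
  if (density <= 0) stop("density must be > 0 kg/m^3")
  if (surface_tension < 0) stop("surface_tension must be >= 0 N/m")
  if (is.na(radial_failure_strain) || radial_failure_strain < 0)
    stop("radial_failure_strain must be >= 0 (use >= 0.5 or Inf for no failure)")
  if (radial_failure_strain >= 0.5) radial_failure_strain <- Inf
  structure(list(elastic_modulus = elastic_modulus,
                 kinematic_viscosity = kinematic_viscosity,
                 density = density,
                 surface_tension = surface_tension,
                 radial_failure_strain = radial_failure_strain),
            class = "lcr_material")
}

#' @export
print.lcr_material <- function(x, ...) {
  cat("<lcr_material>\n")
  cat(sprintf("  elastic modulus       : %g kPa\n", x$elastic_modulus / 1e3))
  cat(sprintf("  kinematic viscosity   : %g m^2/s\n", x$kinematic_viscosity))
  cat(sprintf("  density               : %g kg/m^3\n", x$density))
  cat(sprintf("  surface tension       : %g N/m\n", x$surface_tension))
  cat(sprintf("  radial failure strain : %s\n",
              if (is.infinite(x$radial_failure_strain)) "none (never fails)"
              else format(x$radial_failure_strain)))
  invisible(x)
}

#' Far-field and gas-phase constants
#'
#' Ambient conditions closing the gas law: far-field pressure, the vapor
#' pressure that sets the internal gas pressure at maximum radius, the
#' adiabatic index of the bubble contents, and temperature. Defaults are
#' water at 25 degrees C under one atmosphere, with adiabatic index 4/3
#' (which reproduces the equilibrium-radius relation R0/Rmax =
#' (p_v/p_inf)^(1/4)).
#'
#' @param far_field_pressure Isotropic pressure far from the bubble (Pa).
#' @param vapor_pressure Vapor pressure inside the bubble at maximum radius
#'   (Pa); 3169 Pa for water at 25 degrees C.
#' @param adiabatic_index Adiabatic index kappa (> 1).
#' @param temperature Absolute temperature (K).
#' @return An object of class `lcr_ambient`.
#' @export
ambient_conditions <- function(far_field_pressure = 101325,
                               vapor_pressure = 3169,
                               adiabatic_index = 4 / 3,
                               temperature = 298.15) {
  if (!(vapor_pressure > 0 && vapor_pressure < far_field_pressure))
    stop("need 0 < vapor_pressure < far_field_pressure")
  if (adiabatic_index <= 1) stop("adiabatic_index must be > 1")
  if (temperature <= 0) stop("temperature must be > 0 K")
  structure(list(far_field_pressure = far_field_pressure,
                 vapor_pressure = vapor_pressure,
                 adiabatic_index = adiabatic_index,
                 temperature = temperature),
            class = "lcr_ambient")
}

#' @export
print.lcr_ambient <- function(x, ...) {
  cat("<lcr_ambient>\n")
  cat(sprintf("  far-field pressure : %g Pa\n", x$far_field_pressure))
  cat(sprintf("  vapor pressure     : %g Pa\n", x$vapor_pressure))
  cat(sprintf("  adiabatic index    : %g\n", x$adiabatic_index))
  cat(sprintf("  temperature        : %g K\n", x$temperature))
  invisible(x)
}

#' Equilibrium bubble radius
#'
#' Radius at which the internal gas pressure balances the far field before
#' any elastic stress is applied to the surroundings:
#' `R0 = R_max * (p_v / p_inf)^(1 / (3 kappa))`.
#'
#' @param R_max Maximum bubble radius (m), > 0. Vectorized.
#' @param ambient [ambient_conditions()].
#' @return Equilibrium radius (m).
#' @examples
#' equilibrium_radius(70e-6) * 1e6  # ~29.4 um
#' @export
equilibrium_radius <- function(R_max, ambient = ambient_conditions()) {
  if (any(!is.finite(R_max)) || any(R_max <= 0))
    stop("R_max must be positive and finite")
  R_max * (ambient$vapor_pressure / ambient$far_field_pressure) ^
    (1 / (3 * ambient$adiabatic_index))
}

#' Internal gas pressure
#'
#' Adiabatic gas law referenced to the maximum radius, where the contents are
#' at the vapor pressure: `p_B(R) = p_v * (R_max / R)^(3 kappa)`.
#'
#' @param radius Current bubble radius (m), > 0. Vectorized.
#' @param R_max Maximum bubble radius (m), > 0.
#' @param ambient [ambient_conditions()].
#' @return Pressure (Pa).
#' @export
internal_pressure <- function(radius, R_max, ambient = ambient_conditions()) {
  if (any(radius <= 0)) stop("radius must be > 0")
  if (any(R_max <= 0)) stop("R_max must be > 0")
  ambient$vapor_pressure * (R_max / radius) ^ (3 * ambient$adiabatic_index)
}

#' Neo-Hookean elastic stress of the intact material
#'
#' Elastic stress the intact surroundings impose on the bubble surface:
#' `(eta / 2) * (5 - 4 (R0/R) - (R0/R)^4)`. Zero at the equilibrium radius,
#' negative below it (the compressed cavity is pushed open), and approaching
#' the asymptote `5 eta / 2` as the bubble grows large.
#'
#' @param radius Bubble radius (m), > 0. Vectorized.
#' @param R_0 Equilibrium radius (m).
#' @param elastic_modulus Elastic modulus (Pa).
#' @return Stress (Pa).
#' @export
elastic_stress_intact <- function(radius, R_0, elastic_modulus) {
  if (any(radius <= 0)) stop("radius must be > 0")
  x <- R_0 / radius
  (elastic_modulus / 2) * (5 - 4 * x - x ^ 4)
}

#' Plateau stress after material failure
#'
#' Once the material ruptures at radius `R_f`, further expansion is plastic
#' and the elastic stress stays frozen at its value at failure, i.e. the
#' intact stress evaluated at `R_f`.
#'
#' @param R_f Failure radius (m), >= `R_0`.
#' @param R_0 Equilibrium radius (m).
#' @param elastic_modulus Elastic modulus (Pa).
#' @return Constant plateau stress (Pa).
#' @export
failure_stress <- function(R_f, R_0, elastic_modulus) {
  if (any(R_f < R_0)) stop("R_f must be >= R_0")
  elastic_stress_intact(R_f, R_0, elastic_modulus)
}

#' Elastic stress during post-failure recovery
#'
#' During collapse of a bubble whose surroundings failed, the elastic stress
#' follows the intact functional form rescaled so that it equals the plateau
#' stress `E_f` exactly at the maximum radius (continuity of the plastic and
#' recovery paths) and vanishes at the equilibrium radius.
#'
#' @param radius Bubble radius (m), > 0. Vectorized.
#' @param R_0 Equilibrium radius (m).
#' @param R_max Maximum bubble radius (m), > `R_0`.
#' @param E_f Plateau stress at failure (Pa), see [failure_stress()].
#' @return Stress (Pa).
#' @export
elastic_stress_recovery <- function(radius, R_0, R_max, E_f) {
  if (any(radius <= 0)) stop("radius must be > 0")
  xm <- R_0 / R_max
  den <- 5 - 4 * xm - xm ^ 4
  if (abs(den) < .Machine$double.eps * 10)
    stop("degenerate geometry: R_max equals R_0, recovery stress undefined")
  x <- R_0 / radius
  E_f * (5 - 4 * x - x ^ 4) / den
}

#' Green-Lagrange strains at the bubble wall
#'
#' Finite-strain measures of the material point at the bubble wall, relative
#' to the equilibrium configuration. The radial component is sign-flipped so
#' that compression (bubble expansion) is positive:
#' `eps_rr = -1/2 ((R0/R)^4 - 1)`, `eps_tt = 1/2 ((R/R0)^2 - 1)`.
#' Both vanish at `R = R0`; the radial strain is bounded above by 0.5.
#'
#' @param radius Bubble radius (m), > 0. Vectorized.
#' @param R_0 Equilibrium radius (m), > 0.
#' @return List with numeric components `radial` and `circumferential`.
#' @export
wall_strains <- function(radius, R_0) {
  if (any(radius <= 0)) stop("radius must be > 0")
  if (any(R_0 <= 0)) stop("R_0 must be > 0")
  x <- R_0 / radius
  list(radial = -0.5 * (x ^ 4 - 1),
       circumferential = 0.5 * (1 / x ^ 2 - 1))
}

#' Bubble radius at which the material fails
#'
#' Inverts the radial wall strain for the radius at which it reaches the
#' failure value: `R_f = R0 * (1 - 2 eps)^(-1/4)`. A failure strain >= 0.5
#' can never be reached (0.5 is the asymptote of the radial wall strain), so
#' it returns `Inf` as the explicit "never fails" signal rather than an error.
#'
#' @param radial_failure_strain Radial failure strain (dimensionless, >= 0).
#'   Vectorized.
#' @param R_0 Equilibrium radius (m).
#' @return Failure radius (m); `Inf` where the material never fails.
#' @export
failure_radius <- function(radial_failure_strain, R_0) {
  if (any(is.na(radial_failure_strain)) || any(radial_failure_strain < 0))
    stop("radial_failure_strain must be >= 0")
  out <- R_0 * (1 - 2 * radial_failure_strain) ^ (-1 / 4)
  out[radial_failure_strain >= 0.5] <- Inf
  out
}

#' Circumferential failure strain from the radial one
#'
#' Composes the two wall-strain relations through the failure radius: the
#' circumferential strain when the radial wall strain reaches `eps_rr` is
#' `1/2 ((1 - 2 eps_rr)^(-1/2) - 1)`. Monotone increasing, zero at zero, and
#' diverging as the radial strain approaches its 0.5 asymptote (so a
#' no-failure input maps to `Inf`).
#'
#' @param radial_failure_strain Radial failure strain (>= 0). Vectorized.
#' @return Circumferential failure strain (dimensionless).
#' @examples
#' circumferential_failure_strain(0.25)  # ~0.207, prints as 0.21
#' @export
circumferential_failure_strain <- function(radial_failure_strain) {
  if (any(is.na(radial_failure_strain)) || any(radial_failure_strain < 0))
    stop("radial_failure_strain must be >= 0")
  out <- 0.5 * ((1 - 2 * radial_failure_strain) ^ (-1 / 2) - 1)
  out[radial_failure_strain >= 0.5] <- Inf
  out
}

#' Geometry of one cavitation cycle
#'
#' Derives from the maximum radius the equilibrium radius, the failure radius
#' (if the material can fail), whether failure occurs during the cycle
#' (`R_max > R_f`), and the plateau stress frozen at failure.
#'
#' @param R_max Maximum bubble radius (m), > 0.
#' @param mat [material()].
#' @param ambient [ambient_conditions()].
#' @return An object of class `lcr_geometry` with fields `R_max`, `R_0`,
#'   `R_f` (`Inf` when the material never fails), `failed`, and `E_f`.
#' @export
cycle_geometry <- function(R_max, mat = material(),
                           ambient = ambient_conditions()) {
  if (!is.finite(R_max) || R_max <= 0) stop("R_max must be positive")
  R_0 <- equilibrium_radius(R_max, ambient)
  R_f <- failure_radius(mat$radial_failure_strain, R_0)
  failed <- is.finite(R_f) && R_max > R_f
  E_f <- if (failed) failure_stress(R_f, R_0, mat$elastic_modulus) else 0
  structure(list(R_max = R_max, R_0 = R_0, R_f = R_f,
                 failed = failed, E_f = E_f),
            class = "lcr_geometry")
}

#' @export
print.lcr_geometry <- function(x, ...) {
  cat("<lcr_geometry>\n")
  cat(sprintf("  R_max : %.2f um\n", x$R_max * 1e6))
  cat(sprintf("  R_0   : %.2f um\n", x$R_0 * 1e6))
  cat(sprintf("  R_f   : %s\n",
              if (is.finite(x$R_f)) sprintf("%.2f um", x$R_f * 1e6)
              else "never fails"))
  cat(sprintf("  fails during cycle: %s\n", x$failed))
  invisible(x)
}
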