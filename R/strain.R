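#' Deformed position of a material point
#'
#' Incompressible, spherically symmetric kinematics: the material shell that
#' sat at reference radius `r_ref` (measured in the equilibrium configuration,
#' so `r_ref >= R_0`) moves to `r = (r_ref^3 + R_B^3 - R_0^3)^(1/3)` when the
#' bubble has radius `R_B` — the volume between the bubble wall and the shell
#' is conserved.
#'
#' @param r_ref Reference radial position (m), >= `R_0`. Vectorized.
#' @param R_B Current bubble radius (m).
#' @param R_0 Equilibrium bubble radius (m).
#' @return Deformed radial position (m).
#' @export
deformed_radius <- function(r_ref, R_B, R_0) {
  if (any(r_ref < R_0)) stop("r_ref must be >= R_0 (points inside the cavity)")
  (r_ref ^ 3 + R_B ^ 3 - R_0 ^ 3) ^ (1 / 3)
}

#' Finite-strain field around the bubble
#'
#' Green-Lagrange radial and circumferential strains of material points at
#' reference positions `grid * R_0`, evaluated when the bubble has radius
#' `R_B` (the maximum radius by default, where strains peak). At the wall
#' (`grid = 1`) the field reduces to [wall_strains()]; both components decay
#' to zero in the far field, the circumferential one as
#' `(R_B^3 - R_0^3) / (3 r_ref^3)`.
#'
#' @param R_max Maximum bubble radius (m).
#' @param ambient [ambient_conditions()].
#' @param grid Dimensionless reference positions in units of `R_0`, >= 1.
#' @param R_B Bubble radius at which to evaluate the field (m); defaults to
#'   `R_max`.
#' @return data.frame of class `lcr_strain_field` with columns
#'   `r_ref_over_R0`, `radius_ref`, `radius_deformed`, `strain_rr`
#'   (compression positive), `strain_tt`; attributes `R_max`, `R_0`, `R_B`.
#' @export
strain_field <- function(R_max, ambient = ambient_conditions(),
                         grid = seq(1, 8, by = 0.01), R_B = R_max) {
  if (any(grid < 1)) stop("grid positions must be >= 1 (in units of R_0)")
  R_0 <- equilibrium_radius(R_max, ambient)
  r_ref <- grid * R_0
  r <- deformed_radius(r_ref, R_B, R_0)
  out <- data.frame(r_ref_over_R0 = grid,
                    radius_ref = r_ref,
                    radius_deformed = r,
                    strain_rr = -0.5 * ((r_ref / r) ^ 4 - 1),
                    strain_tt = 0.5 * ((r / r_ref) ^ 2 - 1))
  structure(out, R_max = R_max, R_0 = R_0, R_B = R_B,
            class = c("lcr_strain_field", "data.frame"))
}

#' Characteristic strain rate of a cavitation cycle
#'
#' The peak circumferential wall strain divided by the time from cycle start
#' to the apex — the mean rate at which the material is taken to its largest
#' deformation — plus the instantaneous wall strain-rate series
#' `d(eps_tt)/dt = R V / R_0^2` along the trajectory.
#'
#' @param trajectory An `lcr_trajectory`.
#' @return List with `rate` (1/s), `peak_strain`, `time_to_peak` (s) and
#'   `series` (data.frame `time`, `strain_tt`, `rate`).
#' @export
strain_rate_estimate <- function(trajectory) {
  s <- trajectory$states
  if (nrow(s) < 2) stop("trajectory has fewer than 2 states")
  R_0 <- trajectory$geometry$R_0
  peak <- 0.5 * ((trajectory$geometry$R_max / R_0) ^ 2 - 1)
  list(rate = peak / trajectory$T_growth,
       peak_strain = peak,
       time_to_peak = trajectory$T_growth,
       series = data.frame(time = s$time,
                           strain_tt = 0.5 * ((s$radius / R_0) ^ 2 - 1),
                           rate = s$radius * s$velocity / R_0 ^ 2))
}

#' Polymer network mesh size
#'
#' Characteristic pore scale of a crosslinked network from its storage
#' modulus: `delta = (k_B T / G')^(1/3)`. Used to check that the bubble
#' engages the material far above its microstructural scale, justifying the
#' continuum treatment.
#'
#' @param storage_modulus Storage modulus G' (Pa), > 0. Vectorized.
#' @param temperature Absolute temperature (K), > 0.
#' @return Mesh size (m).
#' @examples
#' mesh_size(5e3) * 1e9  # ~9.4 nm
#' @export
mesh_size <- function(storage_modulus, temperature = 298.15) {
  if (any(storage_modulus <= 0)) stop("storage_modulus must be > 0")
  if (any(temperature <= 0)) stop("temperature must be > 0")
  kB <- 1.380649e-23
  (kB * temperature / storage_modulus) ^ (1 / 3)
}
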