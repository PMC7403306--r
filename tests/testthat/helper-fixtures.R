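# shared fixtures: canonical materials and a slow but independent fixed-step
# RK4 integrator used as the oracle for the adaptive cycle solver

fibrin_like <- function(eta = 20e3, eps = 0.25)
  material(elastic_modulus = eta, radial_failure_strain = eps)

inviscid_water <- function()
  material(elastic_modulus = 0, kinematic_viscosity = 0, surface_tension = 0)

# independent cycle-time oracle: classical RK4 at a fixed step on the same
# apex-anchored legs, turning points located by linear interpolation of the
# velocity sign change (refined with the local acceleration)
rk4_cycle_time <- function(R_max, mat, ambient = ambient_conditions(),
                           n_steps = 20000) {
  geom <- cycle_geometry(R_max, mat, ambient)
  Tw <- water_cycle_time(R_max, mat$density, ambient)
  h <- 1.5 * Tw / n_steps
  acc <- function(R, V, phase) bubble_acceleration(R, V, phase, mat,
                                                   ambient, geom)
  growth_phase <- function(R) {
    if (geom$failed && R >= geom$R_f) "plastic_growth" else "elastic_growth"
  }
  run_leg <- function(reversed, phase_of) {
    sgn <- if (reversed) -1 else 1
    f <- function(y) {
      ph <- phase_of(y[1])
      c(y[2], acc(y[1], sgn * y[2], ph))
    }
    a0 <- f(c(R_max, 0))[2]
    eps <- 1e-6 * Tw
    y <- c(R_max + 0.5 * a0 * eps^2, a0 * eps)
    t <- eps
    for (i in seq_len(3 * n_steps)) {
      k1 <- f(y); k2 <- f(y + h / 2 * k1); k3 <- f(y + h / 2 * k2)
      k4 <- f(y + h * k3)
      y1 <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      if (y1[2] >= 0 && y[2] < 0) {
        a <- f(y)[2]
        dt <- -y[2] / a  # series refinement of the crossing
        return(t + dt)
      }
      y <- y1
      t <- t + h
    }
    stop("rk4 oracle found no turning point")
  }
  Tg <- run_leg(reversed = TRUE, phase_of = growth_phase)
  collapse_phase <- if (geom$failed) function(R) "recovery" else
    function(R) "elastic"
  Tc <- run_leg(reversed = FALSE, phase_of = collapse_phase)
  Tg + Tc
}
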