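#' Radius-time dataset
#'
#' Container for measured or synthetic bubble radius-time points with
#' replicate structure: one row per photographed bubble event, identified by
#' delay since the laser pulse and a replicate index.
#'
#' @param time Delays since the laser pulse (s), >= 0.
#' @param radius Bubble radii (m).
#' @param replicate_id Integer replicate index per delay.
#' @param sample_id Sample identifier (single string).
#' @param pulse_energy Optional pulse-energy label (free text).
#' @param gel Optional gel label (free text).
#' @return data.frame of class `lcr_dataset` with columns `time`, `radius`,
#'   `replicate_id`, `sample_id`.
#' @export
lcr_dataset <- function(time, radius, replicate_id = 1L,
                        sample_id = "sample", pulse_energy = NA_character_,
                        gel = NA_character_) {
  if (!length(time)) stop("dataset must contain at least one point")
  if (length(radius) != length(time)) stop("time and radius lengths differ")
  if (any(time < 0)) stop("delays must be non-negative")
  out <- data.frame(time = as.numeric(time), radius = as.numeric(radius),
                    replicate_id = as.integer(rep_len(replicate_id,
                                                      length(time))),
                    sample_id = rep_len(as.character(sample_id), length(time)))
  structure(out, pulse_energy = pulse_energy, gel = gel,
            class = c("lcr_dataset", "data.frame"))
}

#' Parameters of the forward model subject to fitting
#'
#' @param R_max Maximum bubble radius (m).
#' @param elastic_modulus Elastic modulus (Pa).
#' @param radial_failure_strain Radial failure strain; >= 0.5 or `Inf` means
#'   no failure.
#' @param t0 Nuisance time offset between camera delay zero and cycle start
#'   (s).
#' @return List of class `lcr_fit_parameters`.
#' @export
fit_parameters <- function(R_max, elastic_modulus,
                           radial_failure_strain = Inf, t0 = 0) {
  stopifnot(R_max > 0, elastic_modulus >= 0, radial_failure_strain >= 0)
  if (radial_failure_strain >= 0.5) radial_failure_strain <- Inf
  structure(list(R_max = R_max, elastic_modulus = elastic_modulus,
                 radial_failure_strain = radial_failure_strain, t0 = t0),
            class = "lcr_fit_parameters")
}

params_material <- function(params, mat) {
  material(elastic_modulus = params$elastic_modulus,
           kinematic_viscosity = mat$kinematic_viscosity,
           density = mat$density,
           surface_tension = mat$surface_tension,
           radial_failure_strain = params$radial_failure_strain)
}

#' Residuals of a parameter set against a dataset
#'
#' Runs one cycle simulation at the candidate parameters and returns, per
#' data point, model radius at `(t - t0)` minus the observed radius. Points
#' falling outside the simulated cycle window contribute the distance to the
#' radius at the nearest cycle endpoint. If the simulation fails, every
#' residual is set to a large penalty (1 mm) with a warning, which steers the
#' optimizer back into the feasible region.
#'
#' @param params [fit_parameters()].
#' @param dataset [lcr_dataset()].
#' @param mat [material()] supplying the fixed constants (viscosity, density,
#'   surface tension); its modulus and failure strain are overridden by
#'   `params`.
#' @param ambient [ambient_conditions()].
#' @param mode `"failure"` or `"no_failure"` (intact law throughout).
#' @param solver [solver_options()].
#' @return Numeric vector, one residual per dataset row (m).
#' @export
lcr_residuals <- function(params, dataset, mat = material(),
                          ambient = ambient_conditions(),
                          mode = c("failure", "no_failure"),
                          solver = solver_options()) {
  mode <- match.arg(mode)
  sim_mode <- if (mode == "no_failure") "elastic" else "failure"
  tr <- tryCatch(
    simulate_cycle(params$R_max, params_material(params, mat), ambient,
                   mode = sim_mode, solver = solver),
    error = function(e) {
      warning("simulation failed during fitting (", conditionMessage(e),
              "); returning penalty residuals", call. = FALSE)
      NULL
    })
  if (is.null(tr)) return(rep(1e-3, nrow(dataset)))
  trajectory_radius(tr, dataset$time - params$t0) - dataset$radius
}

#' Initial parameter guess from a dataset
#'
#' `R_max` starts at the largest observed radius; the modulus starts from a
#' cycle-shortening heuristic — the observed cycle time relative to the
#' analytic water value is inverted through a small simulated
#' modulus-vs-ratio map computed at a failure strain of 0.25 — and the
#' failure strain starts at 0.25 with zero time offset.
#'
#' @param dataset [lcr_dataset()], at least 4 distinct delays.
#' @param mat,ambient,solver Fixed constants and solver, as in
#'   [lcr_residuals()].
#' @return [fit_parameters()].
#' @export
initial_guess <- function(dataset, mat = material(),
                          ambient = ambient_conditions(),
                          solver = solver_options()) {
  delays <- sort(unique(dataset$time))
  if (length(delays) < 4)
    stop("under-determined data: need at least 4 distinct delays")
  R_max0 <- max(dataset$radius)
  step <- stats::median(diff(delays))
  T_obs <- max(delays) - min(delays) + step
  ratio_obs <- T_obs / water_cycle_time(R_max0, mat$density, ambient)
  eta_probe <- c(0, 10e3, 20e3, 40e3, 80e3)
  ratios <- vapply(eta_probe, function(e) {
    m <- material(elastic_modulus = e,
                  kinematic_viscosity = mat$kinematic_viscosity,
                  density = mat$density,
                  surface_tension = mat$surface_tension,
                  radial_failure_strain = 0.25)
    cycle_time_ratio(simulate_cycle(R_max0, m, ambient, solver = solver))
  }, numeric(1))
  eta0 <- if (ratio_obs >= max(ratios)) 0
          else if (ratio_obs <= min(ratios)) max(eta_probe)
          else stats::approx(ratios, eta_probe, xout = ratio_obs)$y
  fit_parameters(R_max = R_max0, elastic_modulus = eta0,
                 radial_failure_strain = 0.25, t0 = 0)
}

#' Default box bounds for the fit
#'
#' @param dataset [lcr_dataset()] (sets the `R_max` window from the largest
#'   observed radius).
#' @return List with `lower` and `upper` named vectors over
#'   `(R_max, elastic_modulus, radial_failure_strain, t0)`, SI units.
#' @export
fit_bounds <- function(dataset) {
  R_obs <- max(dataset$radius)
  list(lower = c(R_max = 0.9 * R_obs, elastic_modulus = 0,
                 radial_failure_strain = 0, t0 = -2e-6),
       upper = c(R_max = 1.5 * R_obs, elastic_modulus = 200e3,
                 radial_failure_strain = 0.499, t0 = 2e-6))
}

# scale between SI parameters and the conditioned vector seen by the
# optimizer (um, kPa, -, us)
par_scale <- c(R_max = 1e6, elastic_modulus = 1e-3,
               radial_failure_strain = 1, t0 = 1e6)

#' Fit the bubble model to a radius-time dataset
#'
#' Bounded Levenberg-Marquardt least squares of the forward cycle simulation
#' against the observed radii. The full model fits `(R_max, eta, eps_f,rr)`
#' and optionally a nuisance time offset `t0`; the no-failure variant freezes
#' the failure strain at the no-failure flag and fits only `(R_max, eta,
#' [t0])` with the intact law throughout.
#'
#' @param dataset [lcr_dataset()].
#' @param init [fit_parameters()] starting point; default [initial_guess()].
#' @param mode `"failure"` or `"no_failure"`.
#' @param mat [material()] with the constants held fixed during fitting.
#' @param ambient [ambient_conditions()].
#' @param fit_t0 Fit the time offset (default) or freeze it at `init$t0`.
#' @param bounds As returned by [fit_bounds()] (the default).
#' @param control Passed to [minpack.lm::nls.lm.control()]; defaults
#'   `ftol = 1e-10`, `ptol = 1e-8`, `maxiter = 60`.
#' @param solver [solver_options()] used for every residual evaluation.
#' @return Object of class `lcr_fit`: `estimate` ([fit_parameters()]),
#'   `circumferential_failure_strain`, `residual_norm` (m),
#'   `per_point_residuals`, `covariance` (SI units, `NA` when the Jacobian is
#'   singular), `convergence` (iterations, termination code and message,
#'   `converged` flag), `mode`, `n_points`.
#' @export
fit_dataset <- function(dataset, init = NULL,
                        mode = c("failure", "no_failure"),
                        mat = material(), ambient = ambient_conditions(),
                        fit_t0 = TRUE, bounds = fit_bounds(dataset),
                        control = list(), solver = solver_options()) {
  mode <- match.arg(mode)
  if (is.null(init)) init <- initial_guess(dataset, mat, ambient, solver)
  free <- c("R_max", "elastic_modulus",
            if (mode == "failure") "radial_failure_strain",
            if (fit_t0) "t0")
  start_si <- c(R_max = init$R_max, elastic_modulus = init$elastic_modulus,
                radial_failure_strain =
                  if (mode == "failure" &&
                      is.finite(init$radial_failure_strain))
                    init$radial_failure_strain else 0.25,
                t0 = init$t0)
  start_si[free] <- pmin(pmax(start_si[free],
                              bounds$lower[free]), bounds$upper[free])

  build_params <- function(p_scaled) {
    si <- start_si
    si[free] <- p_scaled / par_scale[free]
    fit_parameters(R_max = si[["R_max"]],
                   elastic_modulus = si[["elastic_modulus"]],
                   radial_failure_strain =
                     if (mode == "failure") si[["radial_failure_strain"]]
                     else Inf,
                   t0 = si[["t0"]])
  }
  fn <- function(p) {
    lcr_residuals(build_params(p), dataset, mat, ambient,
                  mode = if (mode == "failure") "failure" else "no_failure",
                  solver = solver) * 1e6  # work in um for conditioning
  }
  # epsfcn = 1e-8 gives a ~1e-4 relative forward-difference step: each
  # residual evaluation is an ODE solve, so steps must stay well above the
  # integrator's noise floor for the Jacobian to be meaningful
  ctrl <- utils::modifyList(list(ftol = 1e-12, ptol = 1e-10, maxiter = 100,
                                 epsfcn = 1e-8), control)
  res <- minpack.lm::nls.lm(
    par = start_si[free] * par_scale[free],
    lower = bounds$lower[free] * par_scale[free],
    upper = bounds$upper[free] * par_scale[free],
    fn = fn, control = do.call(minpack.lm::nls.lm.control, ctrl))

  est <- build_params(res$par)
  r_si <- res$fvec / 1e6
  m <- length(r_si); k <- length(free)
  cov_si <- matrix(NA_real_, k, k, dimnames = list(free, free))
  if (m > k) {
    cov_scaled <- tryCatch({
      sigma2 <- sum(res$fvec ^ 2) / (m - k)
      sigma2 * solve(res$hessian)
    }, error = function(e) NULL)
    if (!is.null(cov_scaled))  # residual units cancel in sigma2 / hessian
      cov_si <- cov_scaled / tcrossprod(par_scale[free])
  }
  converged <- res$info %in% 1:4
  if (!converged)
    warning("fit did not converge (", res$message,
            "); returning best-so-far estimate", call. = FALSE)
  structure(list(
    estimate = est,
    circumferential_failure_strain =
      if (is.finite(est$radial_failure_strain))
        circumferential_failure_strain(est$radial_failure_strain)
      else NA_real_,
    residual_norm = sqrt(sum(r_si ^ 2)),
    per_point_residuals = r_si,
    covariance = cov_si,
    convergence = list(iterations = res$niter, code = res$info,
                       message = res$message, converged = converged),
    mode = mode, n_points = m), class = "lcr_fit")
}

#' @export
print.lcr_fit <- function(x, ...) {
  e <- x$estimate
  se <- sqrt(pmax(diag(x$covariance), 0))
  fmt <- function(name, val, scale, unit) {
    s <- if (name %in% rownames(x$covariance) && is.finite(se[name]))
      sprintf(" +/- %.3g", se[name] * scale) else ""
    sprintf("  %-22s: %.4g%s %s\n", name, val * scale, s, unit)
  }
  cat(sprintf("<lcr_fit> (%s model, %d points, %s)\n", x$mode, x$n_points,
              if (x$convergence$converged) "converged" else "NOT converged"))
  cat(fmt("R_max", e$R_max, 1e6, "um"))
  cat(fmt("elastic_modulus", e$elastic_modulus, 1e-3, "kPa"))
  if (x$mode == "failure") {
    cat(fmt("radial_failure_strain", e$radial_failure_strain, 1, ""))
    cat(sprintf("  %-22s: %.4g\n", "circumferential strain",
                x$circumferential_failure_strain))
  }
  cat(fmt("t0", e$t0, 1e6, "us"))
  cat(sprintf("  residual norm         : %.4g um\n", x$residual_norm * 1e6))
  invisible(x)
}

#' Aggregate several fits into per-parameter summaries
#'
#' One fit per sample, then mean and standard deviation (n - 1 denominator;
#' 0 by convention for a single fit) across samples — mirroring how replicate
#' samples of one gel condition are reported.
#'
#' @param fits List of `lcr_fit` objects.
#' @return data.frame with columns `parameter`, `mean`, `sd`, `n` over
#'   `R_max`, `elastic_modulus`, `radial_failure_strain`,
#'   `circumferential_failure_strain`, `t0` (SI units).
#' @export
aggregate_fits <- function(fits) {
  if (!length(fits)) stop("need at least one fit")
  if (inherits(fits, "lcr_fit")) fits <- list(fits)
  grab <- function(f) c(R_max = f$estimate$R_max,
                        elastic_modulus = f$estimate$elastic_modulus,
                        radial_failure_strain =
                          f$estimate$radial_failure_strain,
                        circumferential_failure_strain =
                          f$circumferential_failure_strain,
                        t0 = f$estimate$t0)
  m <- do.call(rbind, lapply(fits, grab))
  data.frame(parameter = colnames(m),
             mean = colMeans(m),
             sd = if (nrow(m) > 1) apply(m, 2, stats::sd) else
               rep(0, ncol(m)),
             n = nrow(m), row.names = NULL)
}
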