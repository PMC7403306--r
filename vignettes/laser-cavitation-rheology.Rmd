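---
title: "Laser cavitation rheology: model, fitting pipeline and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Laser cavitation rheology: model, fitting pipeline and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cavrheo)
```

## The measurement idea

Laser cavitation rheology infers the mechanical properties of a soft,
water-like material from the dynamics of a single cavitation bubble created
inside it by a focused sub-nanosecond laser pulse. The bubble grows to a
maximum radius of 60–160 µm and collapses again within < 30 µs. An elastic
medium resists that motion, so the oscillation cycle is *shorter* than it
would be in water, and a medium that ruptures resists less than an intact
one. Fitting a bubble-dynamics model to the measured radius–time curve
therefore recovers the elastic modulus and — because rupture leaves its own
signature — the failure strain of the material, at strain rates
(10^4^–10^5^ s^-1^) far beyond any conventional rheometer.

## Governing model

The bubble wall radius $R_B(t)$ obeys a Rayleigh–Plesset-type equation for a
Neo-Hookean viscoelastic medium,

$$R_B \ddot R_B + \tfrac32 \dot R_B^2 =
\frac{p_B - p_\infty}{\rho} - \frac{2S}{\rho R_B}
- \frac{4\nu}{R_B}\dot R_B - \frac{E}{\rho},$$

with gas pressure $p_B = p_v (R_{max}/R_B)^{3\kappa}$ referenced to the
maximum radius, where the contents are at the vapor pressure $p_v$. The
equilibrium radius — the cavity size at which the gas balances the far field
before any elastic stress builds — is $R_0 = R_{max}(p_v/p_\infty)^{1/3\kappa}$.

The elastic stress $E$ switches between three laws over the cycle
(`simulate_cycle()` modes and phases):

* **intact (elastic growth)** — the Neo-Hookean wall stress
  $E_L = \tfrac{\eta}{2}\left[5 - 4\frac{R_0}{R_B} - (\frac{R_0}{R_B})^4\right]$;
* **plastic growth** — once the radial wall strain reaches the failure value
  $\varepsilon_{f,rr}$ at radius $R_f$, the material ruptures and the stress
  stays frozen at the plateau $E_f = E_L(R_f)$;
* **recovery** — during collapse after failure, the intact functional form
  rescaled to equal $E_f$ at $R_{max}$, so the stress is continuous at the
  apex and vanishes again at $R_0$.

Wall strains are Green–Lagrange measures,
$\varepsilon_{w,rr} = -\tfrac12[(R_0/R_B)^4 - 1]$ (sign flipped so
compression is positive) and
$\varepsilon_{w,\theta\theta} = \tfrac12[(R_B/R_0)^2 - 1]$. The radial
strain is bounded above by $0.5$; a failure strain of $0.5$ or more can
never be reached and the package represents it as the explicit no-failure
flag `Inf` (accepted by `material()` and returned by `failure_radius()`),
rather than an error. The model names the *radial* strain as the failure
criterion; the circumferential failure strain is always the derived quantity
`circumferential_failure_strain()`, never an independent parameter.

## Constants the model needs but measurements rarely report

Defaults (all configurable through `material()`, `ambient_conditions()` or
the YAML config):

| constant | default | why |
|---|---|---|
| adiabatic index $\kappa$ | 4/3 | reproduces the equilibrium-radius relation $R_0/R_{max} = (p_v/p_\infty)^{1/4}$ used for the published radii |
| $p_\infty$, $p_v$ | 101325 Pa, 3169 Pa | atmosphere; water vapor pressure at 25 °C |
| $\nu$ | 1e-6 m²/s | water kinematic viscosity; the cycle is inertia-dominated, so its influence on the cycle time is of order 10^-4 |
| $S$ | 0.072 N/m | water surface tension; a few-kPa correction at 50 µm radii |
| $\rho$ | 997 kg/m³ | water density at 25 °C |

Every exported table embeds the constants actually used in its header — the
silence of the literature on $\nu$, $S$, $\rho$ is the main reproducibility
hazard for this class of measurement.

## Solving one cycle

The initial state of a laser-nucleated bubble is not observable, but the
apex is: at $(R_{max}, \dot R_B = 0)$ the state is pinned exactly by the
same parameter that fixes the gas law. `simulate_cycle()` therefore
integrates the *growth* phase backwards in time from the apex (plastic
plateau down to $R_f$, intact law below) and the *collapse* phase forwards
from the apex (recovery law), each until the velocity crosses zero at small
radius, where the adiabatic gas term arrests the motion. The two halves are
concatenated with $t = 0$ at the growth-side turning point, and the cycle
time $T_{hg}$ is the time between turning points. This avoids shooting for
the peak against viscous losses, and guarantees the simulated peak equals
the $R_{max}$ parameter.

Numerical choices:

* `deSolve::lsodar` (adaptive, stiff-capable, with event detection); phase
  switches are located by root-finding on $R_B - R_f$ and $\dot R_B = 0$,
  not per-step conditionals, so the stress is continuous at switch points to
  solver tolerance.
* each leg starts one small analytic series step away from the apex so the
  velocity-zero event does not fire at $t = 0$;
* the maximum internal step is capped at 0.5 % of the analytic water cycle
  time, keeping the integrator honest through the small-radius endgame where
  the gas term grows as $R_B^{-4}$;
* default tolerances `rtol = 1e-9`, `atol = (1e-13 m, 1e-7 m/s)`. An
  independent fixed-step RK4 integration reproduces the cycle time to 0.1 %
  in the test suite.

A reference point: in the inviscid, tension-free, zero-modulus limit the
simulated cycle time lands within 2 % of the Rayleigh closed form
$T_w = 2\times 0.915\,R_{max}\sqrt{\rho/(p_\infty - p_v)}$
(`water_cycle_time()`); the ~1.8 % excess is the physical cushioning by the
internal gas, which the empty-cavity formula ignores.

The experimental definition of "cycle time" (first frame with a bubble to
last, at 1 µs sampling) need not coincide with the turning-point convention
used here; the convention is documented and the endpoints are available from
the trajectory object for any other definition.

## Inverse problem

`fit_dataset()` performs bounded Levenberg–Marquardt least squares
(`minpack.lm::nls.lm`) of the forward simulation against all replicate
points (per-point weighting; a delay-mean option would weight delays
equally, but per-point is the default because replicate counts are near
constant by design). Parameters and bounds:

* $R_{max} \in [0.9, 1.5] \times$ largest observed radius;
* $\eta \in [0, 200]$ kPa;
* $\varepsilon_{f,rr} \in [0, 0.499]$ (frozen at the no-failure flag in the
  `no_failure` variant, which mirrors analyses that ignore rupture);
* a nuisance time offset $t_0 \in [-2, 2]$ µs, fitted by default, because
  the inception time after the laser pulse is not observable.

Starting values (`initial_guess()`): the largest observed radius for
$R_{max}$; $\varepsilon^0_{f,rr} = 0.25$; and the modulus obtained by
inverting a small simulated modulus-versus-cycle-shortening map at the
observed $T_{hg}/T_w$. Residual evaluations that crash the solver return a
1 mm penalty with a warning, which steers the optimizer back into the
feasible region without aborting the fit.

Two numerical details matter far more than usual here, because the
objective surface has a *ridge*: raising $\eta$ while lowering
$\varepsilon_{f,rr}$ (or vice versa) keeps the plateau stress
$E_f = E_L(R_f)$ nearly constant, and the noise-free radii move by only
tens of nanometres along that ridge.

* Trajectory interpolation for residuals is **cubic spline**
  (`trajectory_radius()`), not linear: linear-interpolation error on the ODE
  output grid (~nm) exceeds the along-ridge signal and stalls the optimizer
  off the truth. With splines, fitting noise-free synthetic data returns the
  generating parameters to ~1e-8 relative.
* The forward-difference Jacobian step is set through `epsfcn = 1e-8`
  (~1e-4 relative steps): each residual evaluation is an ODE solve, and
  steps must stay well above the integrator's noise floor.

The ridge also sets what one noisy dataset can and cannot determine. With
the default acquisition (1 µs delays, 5 replicates, 3 % radius noise) the
maximum radius is pinned to well under 1 %, and the plateau stress to
~15 %, but a single fit determines $\eta$ itself only to tens of percent —
the package's Monte-Carlo tests therefore assert an unbiased mean over 20
seeds rather than per-seed accuracy, and per-condition scatter of this
magnitude is what replicate-sample tables of such measurements show.
Fitting failure-generated data with the no-failure model biases $\eta$ low
in every tested condition, which is the signature that motivates modelling
rupture explicitly.

Each dataset (sample) is fitted on its own and `aggregate_fits()` reports
mean ± sd (n − 1) across samples; samples are never pooled into one fit.

## Strain fields, strain rates and mesh size

Only wall strains appear in the governing equation, but the same
incompressible spherically symmetric kinematics that underlie it extend the
strains to material points: a shell at reference position $r_{ref}$ moves to
$r = (r_{ref}^3 + R_B^3 - R_0^3)^{1/3}$ (`deformed_radius()`), giving the
field forms in `strain_field()`. This is the only off-wall extension
consistent with the bubble model itself. The published "radial extent of
significant strain" depends on an unstated threshold; the package exposes
the threshold as a parameter instead of hard-coding a number.

`strain_rate_estimate()` reports the peak circumferential wall strain
divided by the growth time — a mean rate, order 10^5^ s^-1^ for fibrin-like
parameters — plus the instantaneous series. `mesh_size()` implements the
thermal cube-root scaling $\delta = (k_B T / G')^{1/3}$ used to justify the
continuum treatment (9–35 nm pores versus ~100 µm bubbles).

## Synthetic data and imaging

`generate_dataset()` emulates the acquisition: one single-exposure
photograph per bubble event, delays in 1 µs increments, at least five
replicates per delay, one full cycle < 30 µs. Replicate noise is
multiplicative Gaussian with σ = 3 % by default — measurement noise is not
reported for this kind of instrument, so σ is an explicit knob (stated in
every output header), chosen so that synthetic fit scatter is of the same
order as published replicate-sample standard deviations. Delays before
inception or after collapse are omitted rather than recorded as zeros,
because the instrument cannot observe them. What the generator deliberately
does not emulate: shot-to-shot energy jitter, plasma stochasticity,
asphericity, or evolving material damage — so passing recovery tests show
the estimator works under the model's own assumptions, not that real gels
satisfy them.

`segment_frame()` mirrors the standard automated analysis: two-class
k-means on intensities with deterministic initial centers (intensity
min/max, so segmentation is reproducible without a seed and equivariant
under affine intensity rescaling), the darker class taken as the bubble
(configurable polarity), largest connected component kept, holes filled,
and the equivalent radius $r = s\sqrt{A/\pi}$ from the pixel area $A$ and
scale $s$. Frames whose bubble touches the border are flagged and excluded
from series by default (radius underestimation risk); frames with class
centers closer than three pooled within-class standard deviations return a
flagged no-bubble result instead of an error. `render_synthetic_frame()`
provides the matching instrument stand-in (blurred dark disk plus noise) so
the whole imaging path is testable: rendered radii are recovered within one
pixel across the tested blur/noise range.

## Problem sizes used in the shipped checks

The test-suite and acceptance studies use one cycle per simulation
(~100–160 output states), datasets of ~20–110 rows, 20-seed Monte-Carlo
recovery, a 5 × 6 sensitivity grid, 10 bias-direction conditions and 50
imaging round-trip trials — sizes chosen to exercise every code path while
each study remains a desk-scale computation.

## Known limitations

* Single cycle only: rebounds, acoustic emission, non-spherical modes and
  nearby boundaries are out of scope.
* Strain-hardening, rate-dependent yield and other hyperelastic families
  (Mooney–Rivlin, Ogden) are not modelled; thermal and mass transfer in the
  bubble are neglected, as appropriate for inertia-dominated dynamics.
* Which strain component triggers rupture is ambiguous in this class of
  models; the package standardizes on the radial wall strain (the fitted
  quantity) and derives the circumferential value from it.
* $\nu$ and $S$ are held fixed during fitting; they are not identifiable
  from cycle-time data in the inertial regime.
* The simulated cycle-time ratio at published fitted parameters runs ~2.5 %
  above published experimentally measured ratios, consistent with a
  first-frame/last-frame experimental cycle-time convention at 1 µs
  sampling; the package reports the turning-point value and leaves the
  convention configurable downstream.
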