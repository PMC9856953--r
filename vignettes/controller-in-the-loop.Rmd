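---
title: "A controller-in-the-loop test bench for feedback-controlled magnetic hyperthermia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A controller-in-the-loop test bench for feedback-controlled magnetic hyperthermia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhtsim)
```

## What the package simulates

Magnetic hyperthermia therapy (MHT) deposits heat in tissue through
magnetic nanoparticles (MNPs) driven by an alternating magnetic field
(AMF). A clinical-grade device closes a loop around that heat source: a
fiber-optic probe measures temperature at the target, a PID algorithm
converts the setpoint error into a feedback voltage, the voltage commands
the field amplitude of the induction coil, and independent safety sensors
can cut power entirely. `mhtsim` reproduces this loop in software so that
control strategies, gain choices, safety settings and dosimetry can be
exercised at desk scale, without hardware, against reduced-order thermal
plants.

One simulated session is a fixed cycle at the control cadence (1 s, the
logging rate of such devices):

1. **sense** — each sensor applies its first-order lag, fixed bias and
   read noise to the local plant temperature; the display value is
   quantised to the probe resolution;
2. **gate** — the safety supervisor compares the displayed readings with
   per-sensor thresholds (inclusive) and denies power until all readings
   drop below threshold minus a configurable deadband;
3. **control** — the PID law computes the feedback voltage from the
   *analog* control-sensor signal;
4. **actuate** — the voltage maps linearly to peak field within the
   calibrated window, subject to the scenario field cap, and to zero
   while the gate denies power;
5. **integrate** — heat sources scale with the commanded field and the
   plant advances through ten 0.1 s substeps.

This ordering is fixed and documented because the composition oracle in
the test suite re-implements it verbatim from the public module
operations.

## The discrete control law

The controller is a positional PID with
`u = clamp(Kp·e + Ki·∫e dt − Kd·dT_f/dt, u_min, u_max)`:

* backward-Euler (rectangle) integral on the 1 s grid;
* derivative **on the measurement**, not the error, through a
  first-order filter (`derivative_filter_tau`, default 2 s) — a setpoint
  change then produces no derivative kick;
* anti-windup by **conditional integration**: the integrator freezes
  whenever the unclamped output is outside the voltage limits and
  integrating would push it further outside. This addresses the
  integral-windup failure mode that forces hardware power supplies to
  trip during saturated ramps;
* an optional input low-pass (`input_filter_tau`, default 0 s off;
  presets use 3 s). Hardware controllers digitise an analog temperature
  signal and filter it in DSP before the control law; the simulated loop
  needs the same stage. Without it, sensor noise enters the derivative
  term as alternating voltage kicks, and because power is quadratic in
  voltage and the output clamps at zero, the *negative* kicks are
  clipped while the positive ones heat — a rectification that slowly
  ratchets the plant above the setpoint. A 3 s input filter suppresses
  the effect with negligible cost in loop bandwidth at these time
  scales.

For the same reason the engine feeds the controller the conditioned
analog signal (lag + bias + noise) while the session log records the
0.1 °C-quantised display readings: that is how the physical signal chain
behaves, and driving a derivative term from a display-quantised signal
would inject one-count square kicks that the real device never sees.

Gain units are V/°C, V/(°C·s) and V·s/°C. The shipped presets carry the
gain triples of the reference device: gel verification
(0.23, 1e-4, 2.84); liver single-source (0.2, 1e-5, 2.5); liver
distributed-source (0.5, 1e-6, 2.5); tuned canine (2, 1e-4, 2.5). The
single-source liver triple is reported differently in two places in the
source material (gains body text vs. figure caption); both variants are
shipped as presets and neither is declared canonical — the figure-caption
triple drives the `liver_single_*` presets, the body-text triple the
`liver_triple_*` ones.

## Actuator and heat sources

The voltage→field map is linear between `v_zero` and `v_full` and clamps
outside; the reference calibration is 0–1.25 V ↔ 0–9.8 kA/m peak at
160 kHz, while the hardware control signal spans 0–5 V. Whether the
physical map stays linear above 1.25 V is not documented; clamping is
assumed. Scenario field caps (8 and 10 kA/m for the two in vivo
sessions) are enforced in the map itself.

Volumetric heating:

* **MNP**: `P = SLP_ref (H/H_ref)² c_Fe`, quadratic below the reference
  field (linear-response regime) and capped above it to avoid unbounded
  extrapolation — the source material gives no SLP(H) law. The default
  deposit is 80 mg Fe/mL spread as a Gaussian of σ = 3 mm for radial
  plants.
* **Cu wire**: the verification standard; `P = SAR_Cu ρ_Cu` at the
  reference field, with the same quadratic field scaling applied by the
  engine (induced heating is quadratic in H at low field). Matching
  `SLP·c_Fe = SAR_Cu·ρ_Cu` makes the two sources interchangeable, which
  is exactly why a wire standard can verify an MNP controller.
* **Eddy currents**: `P(r) = prefactor · σ_e (μ0 π f H r)² / 2`, the
  classical induced-current closed form; only the proportionality
  `σ(Hfr)²` is documented, so the shape factor is configurable
  (default 1). `hf_compliance()` checks the strict consensus exposure
  limit `H·f < 4.85e8 A/(m·s)` for a 30 cm torso diameter.

## Plants and their calibration

Full-device studies back their gain choices with 3-D finite-element
electromagnetics and heat transfer on segmented anatomy. That is out of
scope here by design; the package substitutes two reduced-order plants
that retain everything the *controller* can observe:

* a **lumped FOPDT node** `dT/dt = (K_gain·P_delayed + T0 − T)/τ_p`
  (exact exponential update, transport delay, optional coupling to a
  core node), and
* a **1-D radial Pennes model** (sphere or cylinder, cell-centred finite
  volumes, backward-Euler, symmetric positive-definite system solved by
  a cached Cholesky factorisation; `dt = Inf` solves the steady state
  directly). Tissue property defaults are k = 0.5 W/(m·°C),
  ρ = 1050 kg/m³, c = 3600 J/(kg·°C), ρ_b c_b = 3.8e6 J/(m³·°C),
  ω_b = 0.004 s⁻¹ (perfused brain) or 0 (ex vivo), T_a = 37 °C — stated
  surrogates, not values from the reference device's (unpublished)
  property table.

The preset lumped constants are **calibration constants, not tissue
properties**. A probe a millimetre or two from a wire or particle
deposit sees a near-field response whose virtual full-drive asymptote
(`K_gain · P_full`, hundreds to tens of thousands of °C) is far above
anything the controlled loop visits; only two combinations matter on
session time scales — the maximum heating rate `K_gain·P_full/τ_p`
(°C/s at full field) and the loss rate near the hold point. Both were
set, per scenario, so that the closed loop with the device's published
gain triples reproduces the device's reported closed-loop behaviour:
sub-minute rise and settling for gel and liver, CEM43 within 60 ± 5 min
for every liver setpoint/duration recipe, and a ≈120 s ramp to 45 °C
with |T − 45| < 0.1 °C for the tuned canine session. This mirrors how
the physical study itself proceeded (simulation-derived gains refined
against observed responses), and it is the only well-posed way to build
a surrogate when the plant's true parameters are unpublished. The
calibration was fixed before the acceptance expectations were frozen and
is not revisited by tests.

## Sensors

Four-point fiber-optic probes motivate the model: accuracy ±0.3 °C
(fixed per-sensor bias, drawn once within the band or set explicitly),
display resolution 0.1 °C (round half away from zero), response time
< 100 ms (first-order lag, default τ = 0.05 s, updated exactly per
substep) and Gaussian read noise. The noise default is sd = 0.02 °C:
well under the display resolution, as for fiber-optic signal
conditioners of this class, and consistent with the reference device
holding a 2 °C step with < 5 % overshoot — peak-hold metrics over a
30-minute session read the *maximum* of ~1800 display samples, so a
noise sd comparable to the display quantum would alone fabricate a
one-count (5 %) apparent overshoot that the hardware demonstrably does
not exhibit.

## Dosimetry and metrics

CEM43 uses the standard breakpoint convention: R = 0.5 at or above
43 °C, R = 0.25 below — the only pair consistent with the
setpoint/duration recipes (44 °C/30 min, 44.5 °C/22.5 min,
45 °C/15 min → 60 min). Integration is left-rectangle on the logging
grid, matching 1 s sample-and-hold records; samples below a 39 °C floor
contribute nothing by default (set `floor_temp = -Inf` to integrate
everything), so baseline body temperature does not accrue dose.
Percentiles across sensors interpolate linearly between order statistics
(`quantile` type 7), making CEM43T90 reproducible.

Controller metrics follow the control-engineering conventions: rise time
to 90 % of the commanded step with linear interpolation between samples
(the source criterion "rise time < 60 s" never states its operational
definition; first-crossing is ill-posed for non-overshooting responses,
so the stricter 90 % definition is used and reported rise times are not
comparable with the device's printed value); settling into a ±0.5 °C
band, reported as the time of the last sample outside the band;
overshoot as peak excursion above setpoint normalised by the step; and
steady-state error as mean |T − T_ref| over the post-settling samples in
the last 20 % of the session. `performance_report()` scores a session
against the design criteria: rise < 60 s, overshoot < 5 %, settling
< 5 min, steady-state error < 1 %, CEM43 within 60 ± 5 min.

## Identification and retuning

`identify_fopdt()` fits (K, τ, θ) by least squares on the exact discrete
response of a FOPDT system to the logged drive sequence (the delay is
implemented by fractional-sample shifting, so θ is continuous), with a
small multistart over initial time constants. `retune_from_pulses()`
linearises the voltage→power chain about the drive that would hold the
setpoint and applies SIMC rules
(`Kc = τ/(g_u(λ+θ))`, `Ti = min(τ, 4(λ+θ))`, `Td = θ/2`,
`λ = max(θ, τ/8, Δt)`). This is a principled stand-in for the
qualitative between-session retuning described for the reference device,
not a reconstruction of it.

## What passing tests do and do not show

The synthetic sessions emulate: saturated ramps, derivative braking,
anti-windup, sensor lag/bias/noise/quantisation, safety trips with
automatic resume, dead time, perfusion sinks and the quadratic
field→power chain. They do not emulate: heterogeneous and shifting MNP
distributions, temperature-dependent perfusion, probe placement error
beyond a static offset, power-supply dynamics and trip behaviour, coil
field non-uniformity, or 3-D conduction paths. A configuration that
passes every criterion here is therefore a *necessary* screen for a
controller design, not evidence it will meet dose targets in tissue.
Scenario doses landing at 53–60 equivalent minutes rather than exactly
60 are the honest consequence of finite ramps and sub-setpoint holds —
the same reason devices report windows rather than points.

## Numerical choices and degenerate inputs

* Lumped updates are exact exponentials (2×2 symmetric eigen-solve when
  core coupling is active): unconditionally stable for any substep.
* The radial system is assembled volume-weighted and symmetric; the
  Cholesky factor is cached per step size. A configuration with no
  perfusion and no anchoring boundary is singular for the steady-state
  solve and raises a plant fault (the engine truncates the log and
  records it).
* Dead time is a drive FIFO at substep resolution (delays round to the
  nearest substep).
* Quantisation rounds half away from zero, matching display-style
  readouts; ties in the tuning grid rank by settling time, then
  integrated absolute error, then smaller Kd.
* Non-finite measurements fault the controller; missing or non-finite
  safety readings force power-down (fail-safe) rather than erroring.
* Traces must be uniformly sampled (1e-9 relative tolerance on the
  step); dose additivity and the rectangle rule are exact on such grids.

## Problem sizes

The shipped sessions integrate 900–1800 control steps (15–30 simulated
minutes) with ten plant substeps each; a session completes in about one
second on a single core. Radial-plant tests use 60–400 cells, grid
convergence is checked by doubling from 100 to 200 cells, and the
identification study uses two 30 s pulses with 90–150 s cooldowns. These
sizes keep the full verification suite under half a minute while leaving
every mechanism (saturation, braking, trips, dose accumulation)
exercised at the cadence of the real device.

## Known limitations

* The lumped surrogates are input-output calibrations; their constants
  have no tissue-level interpretation, and transferring gain triples
  tuned on them to hardware still requires the pulse-based
  identification step.
* CEM43 on display-quantised readings inherits a one-count bias near the
  setpoint (computing the dose on the analog trace removes it).
* The eddy-current source enters the radial plant only as a static
  periphery-weighted profile; no electromagnetic field solution is
  performed.
* Multi-input (MIMO) and adaptive control, pulse-width power modulation
  and volumetric (voxel) dosimetry are out of scope.
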