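---
title: "lvadsim: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lvadsim: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lvadsim)
```

`lvadsim` chains four models — an ionic cell model, a cross-bridge
myofilament model, a passive constitutive law, and a closed-loop lumped
circulation with a continuous-flow pump — into a desk-scale simulator of
normal, heart-failure (HF), and HF + LVAD hemodynamics. This vignette
explains each model, the parameters that matter, the numerical choices,
and what the package's passing tests do and do not show about real hearts.

## The calcium driver

Excitation–contraction coupling is one-way here: a per-beat intracellular
calcium transient is the sole actuator of the mechanics. Two sources are
available.

*Analytic transient.* `make_transient()` evaluates a bi-exponential
`Ca(t) = Ca_dia + A (e^(-t/tau_d) - e^(-t/tau_r)) / M` where `M`
normalizes the bi-exponential so that `max(Ca) = Ca_dia + A` exactly
(the closed-form peak time `t* = ln(tau_d/tau_r) tau_r tau_d /
(tau_d - tau_r)` is inserted into the sampling grid so the sampled peak is
exact, not merely close). Defaults — diastolic 0.1 µM, amplitude 0.9 µM,
rise 20 ms, decay 150 ms, cycle length 800 ms — were chosen once to
resemble the paced human ventricular myocyte's transient; they are artifact
choices, not fitted quantities.

*Ionic model transient.* `pace_to_steady_state()` paces the ten
Tusscher–Noble–Noble–Panfilov (2004) human ventricular cell model
(epicardial variant by default; endo/mid variants differ in `I_to`/`I_Ks`
as published) for 10 beats and `extract_calcium_transient()` converts the
last beat to µM. The transcription keeps the published constants; two
documented touches are ours: the steady-state of the Ca-dependent
inactivation gate is clamped at 1 (the published expression reaches 1.05
at very low calcium, violating the gate's state space by a hair), and gate
updates switch from forward Euler to the exponential (Rush–Larsen) form
whenever `dt > tau/5`, because the fast Na activation gate's time constant
(~1 µs at rest) is far below any practical step. The voltage and
concentration updates remain forward Euler at the protocol's dt = 0.01 ms.
The stimulus convention is inward-negative: `dV/dt = -(I_ion + I_stim)`
with a default of −52 pA/pF for 1 ms.

*Heart failure* is imposed on the transient, not inside the ionic model:
`apply_hf_remodeling()` scales the magnitude (peak above diastolic) to 70%
and the decay time constant by ×0.7, leaving diastolic level and rise
kinetics untouched. "Magnitude" is read as peak-above-diastolic so the
resting level is preserved; "time constant" as the decay constant, the
dominant time scale of a transient. The remodeling direction (faster
decay) follows the protocol statement it implements, although failing
myocytes physiologically show slowed decay.

## The monodomain cable

`run_cable()` solves the 1D monodomain equation with second-order central
differences, no-flux ends, and the full ionic model at every node. The
explicit stability bound `dt < c_m beta dx^2 / (2 sigma)` is checked
before stepping. Defaults (100 nodes, dx = 0.01 cm, beta = 1400 cm^-1,
c_m = 1 µF/cm^2, sigma = 2.2 mS/cm) give a working-myocardium conduction
velocity of ~75 cm/s; the `"purkinje"` preset (dx = 0.025 cm,
sigma = 15.4 mS/cm) was calibrated so a plane wave travels at ~200 cm/s,
the clinically observed Purkinje speed — a calibration of this package,
not a literature conductivity. Conduction velocity is measured as the
least-squares slope of distance on activation time over the central half
of the cable, avoiding boundary effects; activation time is the first
upward crossing of −40 mV, linearly interpolated.

## The myofilament model

A Rice-type ODE system: regulatory units switch between nonpermissive (N)
and permissive (P) conformations; permissive units attach into a
pre-rotation state, rotate into the force-bearing post-rotation state, and
detach hydrolyzing ATP. Tension is the overlap-weighted,
distortion-weighted sum of attached fractions; sarcomere overlap follows
the standard thick/thin filament geometry (1.65/1.2 µm, 0.1 µm bare
zone). Mean distortions obey relaxation equations scaled by steady-state
duty fractions and receive half the sarcomere velocity, which produces the
force–velocity behaviour and the shortening-enhanced ATP consumption.

Deliberate deviations from the published formulation, all load-bearing and
chosen before the validation suite existed:

* rates are quoted per millisecond at a single working temperature
  (310 K); the original's Q10 machinery is dropped;
* the strain-modulated rotation/detachment rates are capped at 5/ms — the
  exponential strain factors otherwise exceed what an explicit stepper at
  dt ≤ 0.1 ms can integrate during rapid shortening; 5/ms is still two
  orders of magnitude faster than twitch time scales;
* the regulatory half-activation is `perm50 = 0.55` (published 0.5).
  With the package's 1.0 µM-peak transient the published value saturates
  the force–calcium curve, so a 30% smaller transient would cost only
  ~35% of tension — far milder contractile failure than the hemodynamics
  this package reproduces imply. With 0.55 the normal twitch is
  submaximal (~95 kPa of a ~117 kPa ceiling) and the HF twitch ratio is
  ~0.33, consistent with the effective end-systolic-elastance ratio that
  the reproduced pressures imply;
* the duplicate no-crossbridge regulatory population of the original
  (used there only for calcium-buffering bookkeeping) is omitted; coupling
  is one-way, so the myofilament never feeds calcium back.

The isometric protocol is available both as a hard length clamp and as the
1000 kPa high-load isotonic limit; at that load the sarcomere settles onto
the stiff collagen segment of the passive curve and moves by less than 1%
during the twitch, so both realizations agree on tension to within 1%
(tested). Isotonic length dynamics use a first-order viscous relaxation
toward the force balance (viscosity 1000 kPa·ms/µm) — a numerical
regularization; the physiological damping comes from the distortion
kinetics. `steady_state_force_ca()` solves the same rate equations
algebraically at fixed calcium (distortion fixed point `x_pre = 0`,
`x_post = x_0`) and serves as the independent reference surface for the
time-marched model.

## The passive material law

`strain_energy()` and `pk2_stress()` evaluate the exponential
(Fung-type) law `W = C/2 (e^Q - 1)` with
`Q = b1 E_ff^2 + b2 (E_rr^2 + E_cc^2 + 2 E_rc^2) + 2 b3 (E_fr^2 +
E_fc^2)` and its closed-form gradient at material points. The constants
C = 2 kPa, b1 = 8, b2 = 2, b3 = 4 map the conventional fiber / transverse /
fiber-shear coefficients onto the exponent in that order; each shear
component is stored once and carries its factor-2 weight inside `Q`. No
volumetric penalty is added — near-incompressibility is a continuum-level
constraint that has no material-point meaning here. Exponents above 700
raise an overflow error naming `Q`.

## The circulation and the pump

Eight compartments in a closed loop: LA → (mitral) → LV → (aortic) →
systemic artery → systemic vein → RA → (tricuspid) → RV → (pulmonary
valve) → pulmonary artery → pulmonary vein → LA. Vessels and atria are
linear compliances (atria with unstressed volumes, so their pressures can
fall below atmospheric under pump suction); valves are ideal diodes
(max(0, ΔP)/R, no inertance, no regurgitation); the LVAD is a pure flow
generator, default 4 L/min, from LV to systemic artery.

Each ventricle is an activation-weighted blend
`P(v, a) = a E_es (v - v0) + (1 - a) P_ed(v)` with
`P_ed(v) = A (e^(B (v - v0d)) - 1)`. Two structural choices matter:

* the EDPVR reference volume `v0d` is decoupled from the ESPVR intercept
  `v0`; one shared intercept cannot put a steep diastolic wall at
  ~100–110 mL and systolic pressure generation at 55–90 mL at the same
  time;
* activation couples to the myofilament tension waveform (isometric twitch
  tension normalized by the normal-condition peak) through a per-ventricle
  Michaelis saturation `a_v = (1 + k) a / (a + k)`. The LV is linear
  (k = ∞). The RV uses k = 0.5, so its pressure generation saturates at
  submaximal tension: under the HF transient (tension ratio 0.33) the RV
  retains ~0.6 of its elastance while the LV retains 0.33. This asymmetry
  — a thin-walled ventricle less sensitive to graded loss of myofilament
  tension — is what lets one shared activation waveform reproduce the
  observed pattern of severe left-sided failure with milder right-sided
  failure. A hard saturation (clipping) does the same arithmetic but its
  vertical upstroke creates spurious early-systolic pressure spikes; the
  smooth form does not.

The resistances/compliances are not literature values: the source model
prints none. They were obtained by calibrating the normal condition
against normal-adult targets (LVESP ≈ 110 mmHg, CO ≈ 3.8 L/min, EF ≈ 46%)
under the qualitative constraint that the three-condition experiment
reproduces the directional physiology (HF congestion of left filling and
pulmonary pressures; LVAD right-heart unloading with increased RV
throughput; no LV isovolumetric phases and aorta above LV under the
pump), then frozen into the package defaults and
`inst/extdata/circulation_params.json`. `calibrate_normal()` re-runs the
fit (log-parameterized Levenberg–Marquardt; the finite-difference step is
widened via `epsfcn` so ODE-solver noise does not corrupt the Jacobian).
Absolute magnitudes on the right side are *not* reproduced — a 0D
surrogate has no claim on the absolute pressures/volumes of a 3D
finite-element ventricle — and two calibration artifacts are worth
knowing: the arterial compliance is large (the volume shift between
conditions, which drives venous congestion under HF and venous relief
under the pump, required a large arterial reservoir), so aortic pulse
pressure is lower than physiological; and baseline right-sided pressures
sit below typical catheterization values.

Integration: `lsoda` (rtol = atol = 1e-7) with the diode kink smoothed by
a conjugate `(ΔP + sqrt(ΔP² + w²))/2R`, w = 0.01 mmHg, to avoid valve
chatter; a fixed-step RK4 mode with exact diodes is kept for
reproducibility and valve-complementarity checks. Default 25 cycles at
BCL 800 ms; steady state is verified, not assumed — the runner reports the
last-two-beat EDV change and warns above 1%.

## The hemodynamic summarizer

From a beat-aligned slice: EDV = max volume, ESV = min volume, EDP =
pressure at first arrival on the EDV plateau (tolerance 1e-6 of the
stroke volume — robust to the sub-microliter drift the smoothed valves
leave during isovolumetric phases), ESP = peak pressure over the beat
(matching the convention in which the normal LV end-systolic value equals
the systolic peak; pressure-at-ESV is available behind
`esp_mode = "at_esv"`), SV/EF/CO by their identities, stroke work as the
shoelace area of the closed loop (the loop is closed by appending the
first sample, with a warning if the endpoint gap exceeds 1% of SV).
Negative EDP is legal and preserved — continuous unloading can pull the
LV below atmospheric pressure.

Isovolumetric phases are intervals where volume is genuinely constant
(instantaneous drift below a third of the 1 mL constancy band *and* total
excursion inside the band) for ≥ 20 ms while pressure moves > 5 mmHg. The
rate criterion alone would misclassify the pump's slow steady drain
(0.67 mL per 10 ms at 4 L/min) as "constant volume".

Valve-opening durations: for the mitral, aortic and pulmonary valves the
natural diode definition (time with flow above 1 mL/s) is used. The
tricuspid valve is special in this architecture: with passive atria, no
inertance and a single large venous reservoir, the systemic venous return
trickles through the open tricuspid for all of diastole, so its nominal
open time tracks diastole length (and HF, with its faster calcium decay
and shorter systole, *lengthens* it). What shortens under HF — and what
one reads off a flux plot — is the width of the tricuspid filling wave,
measured as the time its flux exceeds half its own peak
(`valve_open_durations(..., method = "pulse")`).

`synth_pv_fixture()` builds a smooth four-phase PV loop hitting prescribed
ESP/EDP/EDV/ESV exactly (cosine-ramp phases; optional seeded Gaussian
noise perturbs interior samples only, so the prescribed extremes survive).
It exists so the summarizer is testable without the simulator: round
trips, the shoelace area against independent trapezoidal integration, and
the printed-value arithmetic (EF/CO/PP identities, percent changes) run on
fixtures. What fixture-based tests do *not* show is anything about the
simulator's own loops; those are exercised by the scenario tests.

## What the synthetic conditions do and do not emulate

The generator-side defaults *are* the study conditions: BCL 800 ms, 10
single-cell cycles, 25 integrated cycles, HF scaling 0.7/0.7, pump flow
4 L/min. They emulate steady-state pacing of a remodeled but
structurally fixed heart. They do not emulate: septal interaction between
the ventricles, atrial contraction, valve regurgitation or inertance,
baroreflex or autonomic compensation, coronary flow, mechano-electric
feedback, or any 3D geometry (wall stress, fiber strain maps). Passing
tests therefore demonstrate internal consistency and directional fidelity
of a 0D surrogate, not patient-level prediction.

## Numerical summary

| quantity | value | where |
|---|---|---|
| ionic dt | 0.01 ms (forward Euler; RL gates where dt > tau/5) | cell, cable |
| cable dx | 0.01 cm (0.025 cm Purkinje preset) | monodomain |
| myofilament dt | 0.01 ms, rate cap 5/ms | twitches |
| circulation | lsoda rtol/atol 1e-7, valve smoothing 0.01 mmHg | scenarios |
| problem sizes | 10 cell beats, 25 system beats, 100 cable nodes | protocol |
| fraction conservation | exact to 1e-8 over any run | tested |
| dt-refinement drift | < 1% (cell Ca peak), < 2% (cable CV) | tested |

The problem sizes above are the package's chosen study conditions; all
tests and the acceptance script run them as-is.
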