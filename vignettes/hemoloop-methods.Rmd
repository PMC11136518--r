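---
title: "hemoloop: model, personalization and verification methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hemoloop: model, personalization and verification methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`hemoloop` simulates a closed-loop human circulation with a lumped-parameter
(0D) model and couples it, at every 1-ms tick, to a virtual soft robotic
left-ventricle phantom driven by a two-pump activation controller. This
vignette documents the model equations, the numerical and design choices, the
personalization and tuning procedure, and what the packaged verification does
and does not demonstrate.

## The closed-loop 0D model

The circulation is eight compartments in a loop: left atrium, left ventricle,
systemic arterial and venous compliances, right atrium, right ventricle,
pulmonary arterial and venous compliances, connected by four diode valves and
resistive segments.

**Heart chambers.** Each chamber follows a time-varying elastance
formulation. In diastole the pressure-volume relationship is exponential,

$$P = a\,e^{bV},$$

and in systole it is the linear end-systolic relationship scaled by the
activation,

$$P = E_s\,v_C(t)\,(V - V_0),$$

where $E_s$ (mmHg/ml) is the end-systolic elastance and $V_0$ (ml) the
zero-pressure filling volume. The instantaneous pressure is the convex
combination weighted by the activation value,

$$P(V, t) = v_C(t)\,E_s (V - V_0) + (1 - v_C(t))\,a e^{bV},$$

which reduces exactly to the diastolic law at $v_C = 0$ and to the
end-systolic law at $v_C = 1$ — the standard construction when a nonlinear
diastolic branch is combined with a linear systolic one.

**Activation waveform.** The source hardware prescribes only that $v_C$
ranges from 0 in diastole to 1 in systole; the waveform shape is a design
choice here. We use a raised cosine (half-cosine up, half-cosine down) over a
systolic interval of $0.3\sqrt{60/\mathrm{HR}}$ s — the usual heart-rate
correction of systolic duration — with ventricular onset at the start of the
cycle. The shape parameters (onset, duration) are per-chamber configuration.
The atria reuse the same chamber form with weak elastance; their activation
precedes the ventricular onset by 0.16 of the cycle (a PR-interval fraction)
and lasts 0.10 of the cycle. Whether the source system's atria are active or
passive is unstated; we model them as weakly active because an atrial kick is
needed for realistic late diastolic filling, and the defaults live in the
versioned literature registry (`inst/extdata/registry.yaml`).

**Valves.** Ideal ohmic diodes: flow $(P_{up} - P_{down})/R$ when the
gradient is positive, zero otherwise. No regurgitation, no inertance, no
leaflet dynamics. Because inertance is excluded, the atrioventricular open
resistance is what bounds the peak early-filling (E-wave) flow; the registry
default of 0.02 mmHg s/ml keeps peak mitral flow in the physiologic
400–900 ml/s range with a mean diastolic gradient of 1–3 mmHg. The semilunar
valves use 0.01 mmHg s/ml, placing peak systolic trans-valvular gradients
near 5–10 mmHg.

**Windkessel beds.** Each circulation is a three-element Windkessel plus a
venous compartment: a characteristic resistance $R_c$ (5% of the bed total)
in series upstream of the arterial compliance $C_a$, a peripheral resistance
$R_p$ (95%) to the venous compliance $C_v$, of which a 5% fraction sits
between the venous node and the atrium so venous return is resistive. The
*reported* arterial pressure is the proximal node $P_{C_a} + Q_{valve} R_c$
(aortic root / pulmonary trunk). With that convention the steady-state mean
pressure drop from artery to atrium crosses exactly $R_c + R_p$, so
$(\mathrm{MAP} - \mathrm{RAP})/\mathrm{CO}$ recovers the configured SVR — a
closure property the test suite checks at 5%.

**Integrator.** Fixed-step explicit Euler at $\Delta t = 1$ ms, mirroring
the real-time tick of the hardware-in-the-loop bench. Flows are bookkept
exactly — every flow leaves one compartment and enters another — so total
stressed volume is conserved to rounding error (measured drift
$\sim 10^{-13}$ ml/s against a 0.01 ml/s acceptance bound). A classical
Runge–Kutta 4 option exists for step-refinement checks; halving the step to
0.5 ms changes beat-averaged cardiac output by under 0.2%. The hybrid loop
supports only Euler, because it models a sampled controller, not a smooth
vector field. Degenerate states (NaN, negative volume) abort with a
diagnostic naming the offending compartment.

## Personalization

A clinical record (heart rate, cardiac output, systemic and pulmonary
arterial pressures, right atrial pressure, wedge pressure, CMR ventricular
volumes) maps deterministically to a full parameterization:

* **Vascular resistances** from the clinical relations
  $\mathrm{SVR} = (\mathrm{MAP} - \mathrm{RAP})/\mathrm{CO}$ and
  $\mathrm{PVR} = (\mathrm{PAP_m} - P_{wedge})/\mathrm{CO}$, accepted in
  mmHg·min/l and converted internally to mmHg·s/ml (×0.06). The bed totals
  reproduce these values exactly by construction.
* **Ventricular systolic elastance** $E_s = P_{es}/(\mathrm{ESV} - V_0)$,
  with the end-systolic pressure approximated by the side's systolic
  arterial pressure — a standard clinical proxy, tagged as such in the
  provenance table.
* **Diastolic exponential** $(a, b)$ solved through two points: the
  end-diastolic point $(\mathrm{EDV}, \mathrm{EDP})$ with EDP approximated
  by the wedge pressure (left) or RAP (right), and the anchor
  $(V_0,\ 0.5\ \mathrm{mmHg})$. The anchor makes the two-unknown exponential
  identifiable from a single printed clinical point; $V_0$ itself is not
  clinically identifiable and defaults to 5 ml per ventricle.
* **Arterial compliances** initialised as stroke volume over pulse pressure;
  venous compliances (60 and 15 ml/mmHg) from the literature registry.

Every parameter carries a provenance tag (`measured`, `fitted`,
`literature`).

The three packaged profiles (HFpEF, healthy volunteer, DCM) ship as YAML
records holding the clinical columns of the bench validation. Per-patient
heart rates are not part of the published record; they are recovered from
the identity $\mathrm{CO} = \mathrm{SV} \times \mathrm{HR}$ on the printed
CO and LV volumes (67, 79 and 61 bpm), which reproduces the documented
61–79 bpm range exactly at its endpoints. The healthy profile's wedge
pressure was not measured clinically; the record carries the bench
personalization target of 10 mmHg.

### Automated tuning

The tuned circulatory parameter values of the source system are not
published, so the package provides a deterministic coordinate-descent loop
(`tune_model()`) over the quantities personalization cannot pin down:

* total circulating stressed volume (split over the venous reservoirs in
  proportion to their compliances), driven until the simulated mean left
  atrial pressure meets the wedge-pressure target (gain 30 ml/mmHg, capped
  at ±150 ml per sweep);
* each arterial compliance, rescaled multiplicatively to match the measured
  pulse pressure.

Measured quantities — elastances, resistances, heart rate — are never
touched. Convergence typically takes 5–10 sweeps of short (6 + 3 cycle)
trial runs. Because the closed loop has a single volume-like degree of
freedom, left- and right-sided filling pressures cannot be targeted
independently once the heart properties are fixed; the loop targets the
left side (which controls LV volumes) and accepts the resulting RAP. This
is visible in the HFpEF profile, where simulated RAP undershoots the
clinical 15 mmHg.

## The virtual phantom and the two-pump controller

The phantom is a passive compliant chamber with a quadratic transmural wall
law on the stressed volume $x = V - V_0$:
$P_{int} - P_{ext} = c_0 + c_1 x + c_2 x^2$, with the unstressed volume
equal to the patient's end-systolic LV volume (the mold geometry). The
static characterization protocol is simulated on the bench grid — fills of
0–100 ml in 10-ml steps, external pressures −50 to 150 mmHg in 25-mmHg
steps — and `fit_compliance()` recovers the law by pooled second-order
least squares; the scalar compliance $C$ is the reciprocal of the mean
tangent slope over the operating range. The three packaged wall laws are
*synthetic* (the bench phantoms' regression coefficients are not published)
and are labelled as such in their filenames and documentation.

At every tick the hybrid loop: (i) evaluates the elastance laws at the
current LV volume to produce the target pressure; (ii) commands the internal
pump with a proportional volume-tracking law
$Q = k\,(V_{target} - V_{achieved})/\Delta t$ (default $k = 0.8$; the real
controller's internals are not described, so the decomposition — internal
pump tracks volume, external pump applies the compliance relation — follows
the bench description with gains as configuration); (iii) commands the
external pressure as $P_{ext} = P_{lv} - (V_{lv} - V_{lv,s})/C$. Two modes
exist: `"scalar"` implements that literal relation, while the default
`"local"` mode inverts the full quadratic law (equivalently, uses the
tangent compliance at the commanded volume); the two coincide for a linear
wall. Both pump commands pass through a first-order actuator lag (default
2 ms) and a saturation at the 633 ml/s (38 l/min) pump design flow; (iv) the
achieved internal pressure replaces the LV pressure in the in-silico
mitral/aortic valve-flow computation — the phantom itself has no valves.

With an ideal actuator (no lag, no limit, $k = 1$) the hybrid loop
reproduces the pure in-silico run to machine precision, the equivalence the
acceptance suite checks at 1%. With the default actuator, beat-averaged LV
volumes track the pure run within 2 ml on all profiles; the E-wave filling
transient briefly saturates the pump (the hardware was sized for the healthy
profile), which is logged and flagged without loss of tracking. Tracking
error beyond 20 ml aborts the run. Measurement noise on the internal
pressure is Gaussian, off by default, and requires an explicit seed; seeded
runs are bit-reproducible. The deep negative end-systolic pressure spike of
the physical DC-motor controller is not reproduced by default.

## Verification conventions

`summarize_run()` averages per-beat extrema and means over 20 post-transient
cycles (the bench recording length): cardiac output as mean aortic valve
flow (cross-checked against SV×HR within 1%), ESV/EDV as averaged per-beat
volume minima/maxima, and mean left atrial pressure as the wedge-pressure
surrogate. `nominal_error()` is $|sim - clin|/clin \times 100$ to one
decimal with half-up rounding — the convention that reproduces the
published error cells; the error denominator is the clinical value (e.g.
$0.3/4.1 = 7.3\%$). `kpi_check()` applies the published agreement
thresholds — 10% for pressures and flows, 20% for volumes — and excludes
systemic arterial pressure from the verdict, because the model simulates a
single lumped systemic compartment while the clinical reference is a radial
artery measurement; exclusions are listed, not hidden.

The packaged reference tables
(`inst/extdata/reference_hemodynamics.csv`, `reference_echo.csv`) carry the
published clinical/simulated/error triplets. 43 of the 51 error cells are
exactly reproducible from the two printed values under the half-up
convention; the remaining 8 derive from unrounded internal values and are
flagged `determinable = FALSE` rather than forced.

## Problem sizes and what the tests show

The suite runs short simulations (typically 6–10 analysis cycles after 5–8
transient cycles) for the property checks and the full 10 + 20-cycle
protocol for the end-to-end volume check; the acceptance script runs the
full protocol on all three profiles (about 15 s each including tuning).
Beat-to-beat EDV variation after the transient is required below 1%.

The synthetic phantom laws and the literature registry emulate the
*structure* of the bench (quadratic passive wall, pump limits, activation
timing), not any particular physical phantom: passing tests demonstrate the
internal consistency of the simulator — conservation, controller identity,
hybrid/pure equivalence, personalization closure, reproduction of the
published error arithmetic, and volume errors within the published
agreement band — but not agreement with new measurements on physical
hardware, image-derived volumes, or the unpublished tuned parameter set of
the source bench. Pressure-side errors of the untuned/partially tuned
profiles (notably CO and RAP for HFpEF) can exceed the 10% hemodynamic
threshold; the KPI ledger reports them as failures rather than widening the
band.

## Known limitations

* Explicit Euler at 1 ms is adequate for these parameter ranges (verified by
  step refinement) but stiff parameterizations — very low valve resistances
  or very stiff chambers — may need the RK4 option or a smaller step.
* No baroreflex, no respiratory modulation, no valve regurgitation or
  inertance, no regional wall mechanics, no imaging synthesis.
* Left- and right-sided filling pressures cannot be tuned independently at
  fixed heart properties (single effective volume knob).
* The phantom model is quasi-static: wall viscoelasticity and the phantom's
  freeze/thaw-dependent material variation are outside the wall law.
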