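---
title: "Models and methods behind ventmotion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ventmotion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ventmotion)
```

ventmotion analyses ventilator waveforms and regional ventilation the way a
neonatal respiratory physiology study would: per-breath lung-motion metrics
(time to peak, maximum slope), lung mechanics and energetics, EIT-style
regional summaries, and the group-comparison statistics layered on top.
Because animal waveform data cannot be redistributed, the package carries a
physical simulator of the measurement chain — a continuous-bias-flow
ventilator, patient circuit and single-compartment preterm lung — so every
stage of the analysis can be exercised against known ground truth.  This
vignette documents the models, the defaults and the numerical choices.

## The circuit–lung model

A continuous-bias-flow, pressure-limited ventilator (the mechanism behind
neonatal T-piece devices and continuous-flow conventional ventilators)
feeds fresh gas at bias flow $F$ (L/min) into a circuit with lumped
compliance $C_{circ}$ (mL/cmH2O).  An ideal relief valve holds circuit
pressure at the set inflation pressure during inspiration and at set PEEP
during expiration.  The lung is a single linear compartment, compliance
$C_{rs}$, filling through a resistance $R_{aw}$:

$$
C_{circ}\,\frac{dP_{circ}}{dt} = F - Q - Q_{valve}, \qquad
\frac{dV}{dt} = Q = \frac{P_{circ} - \mathrm{PEEP} - V/C_{rs}}{R_{aw}},
$$

with $P_{ao} = P_{circ}$ the airway-opening pressure, $Q$ the measured flow
and $V$ the volume above the end-expiratory level.  Phase switching is
clock-driven (set Ti and rate): the modelled subject is apnoeic and
intubated, so there is no spontaneous-effort or triggering model.

Two properties follow directly and drive everything the package measures:

* **Flow-limited pressure rise.**  While the valve is below its limit the
  whole bias flow divides between charging the circuit and filling the
  lung, so airway pressure ramps at a rate proportional to $F$.  Time to
  peak pressure/volume lengthens, and maximum slopes shrink, as $F$ falls.
* **Capacitive flow divider.**  During the charging ramp the flow into the
  lung settles at $F\,C_{rs}/(C_{rs}+C_{circ})$, and it can never exceed
  $F$ when a breath starts from circuit pressure = PEEP.  Peak inspiratory
  flow therefore *approximates* the set bias flow only insofar as the
  circuit is stiff relative to the lung; with a realistic circuit the model
  places it 15–20% below the set flow.  This is a known, deliberate
  limitation of the ideal-relief-valve abstraction — real flow-titrating
  ventilators shape the delivered flow more aggressively than a passive
  valve can.

### Exact piecewise integration

Within each valve regime the system is linear and time-invariant, so the
solver integrates each stage in closed form rather than stepping an ODE:
during charging the mode $u = (P_{circ}-\mathrm{PEEP}) - V/C_{rs}$ relaxes
exponentially with the fast time constant
$R_{aw} C_{circ} C_{rs}/(C_{circ}+C_{rs})$ while total stored gas ramps as
$F t$; after the valve clamps, and during expiration, the lung relaxes
with $\tau = R_{aw} C_{rs}$.  The only numerical step is locating the clamp
time as the root of a monotone scalar function (`uniroot`, tolerance
1e-12 s).  The result is exact to floating-point precision at every output
sample, which is why the test suite can hold the simulator to a brute-force
10-microsecond explicit-Euler integration
(`simulate_ventilation_euler()`) at 0.5% in tidal volume and 2 ms in
time-to-PIP: the Euler path is an independent re-derivation, not a second
call into the solver.

### Default study conditions

The simulator's defaults describe the system the analysis is meant for — a
poorly compliant late-preterm lamb on a lung-protective strategy:

| parameter | default | why |
|---|---|---|
| weight | 2.5 kg | late-gestation preterm lamb |
| $C_{rs}$ | 1.25 mL/cmH2O (0.5/kg) | surfactant-deficient preterm respiratory system |
| $R_{aw}$ | 0.025 cmH2O·s/mL | narrow endotracheal tube + airways; $\tau \approx 31$ ms |
| PEEP / PIP | 8 / 22 cmH2O | lung-protective PEEP; PIP titrated so $V_T \approx 7$ mL/kg |
| Ti / rate | 0.5 s / 60 min$^{-1}$ | conventional neonatal settings |
| PIP ceiling | 40 cmH2O | protocol safety limit |
| $C_{circ}$ | 0.3 mL/cmH2O | rigid low-volume neonatal circuit |
| bias flows | 4 / 6 / 8 L/min | the study arms under comparison |

$C_{circ}$ deserves a note.  With the capacitive divider above, a soft
circuit ($C_{circ}$ of order $C_{rs}$) cannot bring airway pressure to the
set PIP within a 0.5-s inspiration at 4 L/min, and the flow groups would no
longer be matched for tidal volume and driving pressure — yet matched
groups reaching the pressure plateau at every flow is precisely the regime
the analysis targets.  A stiff 0.3 mL/cmH2O circuit reproduces that regime
while remaining physically plausible, so it is the default; it is a plain
argument for anyone modelling a softer circuit.

Sensor noise defaults (cohort generation) are additive Gaussian at roughly
1% of full scale: 0.1 cmH2O on pressure, 0.05 L/min on flow, 0.15 mL on
volume, seeded and per-channel.  Unit tests run noise-free; noise matters
for the motion metrics because "time to peak" on a signal with a flat
plateau is otherwise degenerate — with noise it becomes the time the signal
enters its noise-limited plateau, which is the quantity a bedside
measurement actually captures.

### CO2 kinetics and the protocol controller

Gas exchange is emulated, not estimated: alveolar minute ventilation is
$V_A = \mathrm{rate}\times\max(V_T - V_D, 0)$ and PaCO2 relaxes
first-order (default $\tau$ = 60 s) toward $k_{CO2}/V_A$, saturating at an
apnoeic ceiling (130 mmHg) when $V_A = 0$.  The default
$k_{CO2} = 36000$ mmHg·mL/min puts the equilibrium at ~50 mmHg under the
default ventilation.  The closed-loop controller (`run_protocol()`) mimics
intermittent blood-gas-driven care: every interval (default 30 s standing
in for slower clinical cycles) PIP steps ±1 cmH2O toward the tidal-volume
target and rate steps ±5/min toward the PaCO2 band, Ti fixed, ceilings
enforced, every action logged.  Surfactant is modelled only through its
mechanical consequence — a multiplicative compliance step — because only
that consequence is analysed downstream.

## Breath analysis

Breaths are segmented on the flow channel (crossings of ±0.1 L/min with
hysteresis; ~1% of a typical bias flow), so the analyzer is agnostic to the
generating device.  For crossing detection only, the flow is smoothed with
a centered 7-sample moving average — without it, sensor noise near the
zero-flow baseline fabricates breaths; all metrics are computed on the raw
channels.  The onset index is the crossing sample itself (the last sample
at or below threshold) so that pressure and volume read there still
reflect the end-expiratory state.

Derivatives for the maximum-slope metrics use a centered Savitzky-Golay
filter, window 7 samples, order 2 (both configurable).  Raw differences
are noise-dominated at realistic sampling rates; the filter's bias is
bounded on analytic signals (quarter-cycle sine: < 1%) and the estimator
is validated against a central-difference oracle on simulator traces
sampled fast enough (2 kHz) that no feature is sub-sample.  Ties — exact
or within floating-point residue — break to the earliest sample for both
peaks and slopes.  Expiratory "maximum slope" is the maximum *magnitude*
of the derivative, since expiratory change is negative-going.

## Mechanics and energetics

Per breath: PIP, PEEP measured at inspiratory onset (robust to intrinsic
PEEP), $\Delta P$, $V_T$, ratio compliance $C_{dyn} = V_T/\Delta P$ per kg,
and peak inspiratory flow.  A regression alternative is provided by
`fit_eom()`, a least-squares fit of the single-compartment equation of
motion $P_{ao} = V/C + R\,Q + P_0$ over whole breaths; both compliances
are reported because studies differ in which they use.  Rank-deficient
designs (volume and flow linearly dependent) are rejected rather than
silently regularized.

Energetics, with 1 cmH2O·mL = 98.0665e-6 J:

* `energy_per_breath()`: inspiratory $\int (P_{ao}-\mathrm{PEEP})\,dV$
  (trapezoidal).  PEEP-referenced to isolate tidal energy; an
  atmosphere-referenced variant is a flag.  The elastic bound
  $E \ge V_T^2/2C$ holds for any resistive breath and is approached in the
  quasi-static limit.
* `mp_tidal()`: $E_{breath} \times$ rate / weight (J/min/kg).
* `me_rs()`: $0.5\,\Delta P\,V_T + \mathrm{PEEP}\,V_T$ per kg.  This
  closed elastic form is a documented stand-in — the published
  supplementary formulas for these quantities are not reproduced here — and
  is swappable (`form` argument) without touching callers.
* `vei()`: $K/(\Delta P \times \mathrm{rate} \times \mathrm{PaCO_2})$ with
  the literature constant $K = 3800$, exposed as an argument.

Static PV analysis interpolates total lung capacity at 35 cmH2O per kg
(flagged if extrapolated) plus chord compliances;
`static_pv_maneuver()` generates the matching inflation limb from the
model lung ($V = C_{rs} P$ with exponential approach during each hold).
`calibrate_delta_vl()` applies the linear impedance-to-volume scale from a
static-maneuver reference point, as EIT volume calibration is done in
practice.

## EIT regional metrics

The synthesizer projects the global volume signal onto a ground-truth
regional map (per-pixel share of compliance over a two-ellipse lung mask,
with configurable ventral–dorsal gradient and right-lung share), resampled
at 48 frames/s with optional pixel noise.  This emulates functional EIT
*after* reconstruction and respiratory-domain filtering; reconstruction
itself, cardiac-domain signals, electrode artifacts and genuinely
multi-compartment mechanics are outside the generator, so passing tests
validate the analysis arithmetic, not robustness to reconstruction error.

The tidal image is end-inspiratory minus end-expiratory pixel values
averaged over breaths, negatives clipped and counted.  Center of
ventilation is the amplitude-weighted centroid of the tidal distribution,
expressed as % of the lung-mask bounding box (0% most ventral or
subject-right; row 1 of a grid is the most ventral row, column 1 the
subject's right).  The field's "geometric center" is read as this
centroid — the standard EIT CoV; a literal log-scale geometric mean is
available behind `method = "geometric"`.  Relative aeration is a region's
signal share over its pixel share (its size-weighted mean over any
partition is identically 1).  The unventilated ("silent") fraction counts
lung pixels below 10% of the mean non-zero amplitude by default — a
convention, since no universal threshold exists; both the fraction and the
absolute threshold used are reported.

## Cohort statistics

The comparison layer mirrors a three-arm animal study: two-tailed Welch t
tests for two groups, one-way ANOVA with Tukey studentized-range post hocs
for three, and a group × time repeated-measures ANOVA (group tested
against the subject-within-group stratum, time and interaction against the
within-subject residual).  The repeated-measures model is the closed-form
balanced decomposition, not REML: the simulated cohorts are balanced and
complete by construction, and unbalanced tables are rejected with guidance
instead of being approximated.  Group contrasts after the
repeated-measures fit use the same studentized-range adjustment on subject
means.  Exactly-null effects report F = 0 (sums of squares below
floating-point residue are treated as zero).  All tests are validated
against brute-force sums-of-squares oracles and their type-I error is
checked by seeded null simulation (200 replicates per test) in the
acceptance suite.

## Problem sizes and determinism

The shipped tests and the acceptance script run entirely on synthetic
data at desk scale, chosen as the smallest sizes at which each property is
stable: single breaths for oracle comparisons, 10-subject cohorts for
parameter recovery, 10 matched lungs × 30 s × 3 flows for the group
contrasts, 200 null replicates for statistical calibration.  Every
stochastic entry point takes a mandatory seed, cohort generation derives
per-subject sub-seeds reproducibly, and `run_pipeline()` writes
fixed-format artifacts so identical seeds yield byte-identical reports.

## Known limitations

* The ideal relief valve caps, and the capacitive divider discounts, peak
  inspiratory flow; absolute peak-flow levels are conservative relative to
  a real flow-titrating ventilator (direction and ordering across flows
  are unaffected).
* One compartment: no heterogeneous resistance, no intra-breath
  recruitment, no spontaneous effort or asynchrony.
* Pressure is clamped exactly flat at the plateau; real plateaus creep.
  Plateau-timing metrics on noise-free simulated data are therefore
  tie-broken to the earliest sample, and cohort analyses include sensor
  noise.
* CO2 kinetics and the surfactant step emulate physiology for
  controller-testing purposes; their constants are scenario configuration,
  not estimates.
* Oxygenation, hemodynamics and EIT reconstruction are out of scope.
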