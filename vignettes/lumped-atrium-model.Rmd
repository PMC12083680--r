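---
title: "A closed-loop lumped-parameter model of left atrial hemodynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A closed-loop lumped-parameter model of left atrial hemodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atriahemo)
```

## The model

`atriahemo` implements a zero-dimensional (lumped-parameter) model of the
closed circulation built around left atrial (LA) reservoir, conduit and
pump function. Eight storage elements hold the blood volume — four
elastance chambers (LA, LV, RA, RV) and four windkessel compartments
(systemic arterial SA, systemic venous SV, pulmonary arterial PA,
pulmonary venous PV) — connected in the fixed loop

PV → LA → MV → LV → AoV → SA → SV → RA → TV → RV → PuV → PA → PV,

where MV, AoV, TV, PuV are ideal diode valves (linear conductance when
open, zero backflow) and the compartment-to-compartment links are plain
resistors that may carry flow in either direction — the PV→LA resistor in
particular admits the small retrograde pulmonary-vein flow seen during
vigorous atrial contraction. The state vector is the eight volumes, and
each derivative is inflow minus outflow, so total blood volume is
conserved exactly by construction; the suite asserts conservation to
0.1 mL at every sample of every scenario.

### Chamber law

Each chamber blends a linear end-systolic relation
$P_{es}(V) = E_{es}\,(V - V_0)$ with an exponential end-diastolic
relation $P_{ed}(V) = A\,(e^{B (V - V_0)} - 1)$ through a periodic
activation $e(t) \in [0, 1]$. Two gating conventions are implemented in
`chamber_pressure()`:

* **blended** (the Suga–Sagawa convention):
  $P = e\,P_{es} + (1 - e)\,P_{ed}$;
* **additive**: $P = e\,P_{es} + P_{ed}$.

The two LA pressure terms as stated above do not fix a combination
rule, and the choice is a genuinely open design point. The packaged reference circuit
uses **additive** gating: it reads the active and passive terms as
independent pressure contributions, and it keeps the passive wall stiffness —
a material property — present throughout contraction instead of
vanishing at peak activation. Both conventions agree whenever $e = 0$,
which is where all reservoir/conduit behaviour lives.

The four LA constitutive values are fixed literature inputs: baseline
$E_{es} = 0.45$ mmHg/mL, $V_0 = 0$ mL, $A = 0.5$ mmHg,
$B = 0.049$ /mL. The occlusion scenario (`apply_laao()`) overwrites
exactly three of them — $A \to 0.35$, $B \to 0.07$,
$E_{es} \to 0.7$ mmHg/mL — and nothing else. Note the analytic
consequence checked in the tests: both passive curves start with the
same slope $AB = 0.0245$ mmHg/mL at $V_0$, and the post-occlusion curve
dominates everywhere above it.

### Activation

Activation is a squared half-sine on a window expressed in fractions of
the current cycle: zero at the window edges, exactly one at the
midpoint. Ventricular windows start at the beat boundary with duration
0.30 of the cycle; the atrial window (duration 0.20) is timed so its
peak precedes the next ventricular onset by the atrioventricular delay
(0.16 s), putting the atrial kick in late diastole.

The ventricles additionally carry an exponential relaxation tail
(`relax_tau`, default 0.12 s): the upstroke is unchanged, but from the
peak the activation decays as $e^{-t/\tau}$ with an *absolute* time
constant. This matters for rate response. With a pure fraction-scaled
window, relaxation accelerates in proportion to heart rate and diastolic
filling never becomes rate-limited, so cardiac output simply rises with
rate — the opposite of the rapid-ventricular-response physiology the
model is meant to reproduce. An absolute relaxation constant consumes a
growing share of the shortening diastole: at 60 bpm (0.7 s of diastole)
it is barely visible, while at 150 bpm it suppresses early filling and
cardiac output falls. The default 0.12 s sits at the severe end of the
isovolumic-relaxation range reported for elderly patients with diastolic
dysfunction, which is the population the reference circuit represents.
The atria keep the exact squared half-sine.

### Atrial wall viscoelasticity

A purely elastic chamber makes pressure a state function of volume, so
during the reservoir and conduit phases (activation zero) the LA
pressure–volume trajectory retraces one curve and the passive "v-loop"
has zero area — the figure-eight loop shape measured in atria can then
never emerge robustly. The atria therefore carry a small wall
viscoelastic resistance $R_w$ (default 0.01 mmHg·s/mL):
$P = P_{el}(V, e) + R_w\,\dot V$. Filling runs slightly above the
elastic curve and emptying slightly below it, giving the v-loop its
measured hysteresis (clockwise, work done *on* the atrium) opposite in
orientation to the active a-loop. The implicit pressure equation is
solved exactly per atrium (it is piecewise linear and monotone in $P$,
with the mitral/tricuspid diode state resolved consistently);
ventricles stay purely elastic, which keeps each chamber's solve local.
`chamber_pressure()` documents the static (elastic) law; the viscous
term lives in the simulator.

## Reference parameterization

Only the four LA constitutive values are fixed literature inputs; every
other element of the packaged `baseline_circuit()` is a **synthetic
calibrated stand-in**, chosen once to give the left-sided hemodynamics
of an elderly occlusion candidate with diastolic dysfunction at 60 bpm:

| element | parameters (units) | value | rationale |
|---|---|---|---|
| LA | $E_{es}$, $V_0$, $A$, $B$ | 0.45, 0, 0.5, 0.049 | literature inputs |
| LA, RA | $R_w$ (mmHg·s/mL) | 0.01 | reservoir hysteresis scale |
| LV | $E_{es}$, $V_0$, $A$, $B$ | 2.5, 5, 0.35, 0.033 | stiff diastole, EDP ≈ 15 mmHg at 120 mL |
| RA / RV | $E_{es}$, $V_0$, $A$, $B$ | 0.3, 0, 0.4, 0.04 / 0.6, 5, 0.1, 0.025 | right heart, lower pressures |
| LV, RV | `relax_tau` (s) | 0.12 | impaired relaxation, rate-limited filling |
| valves | $R$ (mmHg·s/mL) | MV 0.01, AoV 0.006, TV 0.005, PuV 0.003 | peak mitral E flow ~200–340 mL/s |
| SA | $C$, $R$, $V_u$ | 1.6, 1.0, 300 | arterial windkessel, SVR ≈ 1 |
| SV | $C$, $R$, $V_u$ | 50, 0.05, 2000 | venous capacitance |
| PA | $C$, $R$, $V_u$ | 5.0, 0.10, 50 | pulmonary bed compliance |
| PV | $C$, $R$, $V_u$ | 0.8, 0.01, 300 | stiff distal venous node at the LA inlet |
| total volume | mL | 3600 | sets operating pressures |

At these values a 60 bpm run settles at cardiac output ≈ 4.9 L/min,
aortic pressure ≈ 113/68 mmHg, mean LA pressure ≈ 17–18 mmHg and mitral
E/A ≈ 0.7 (the impaired-relaxation inflow pattern typical of this
cohort). Most of the pulmonary compliance is lumped into the arterial
compartment and the venous node next to the LA is kept stiff, which is
the usual idiom in left-heart-focused lumped networks. Inertial elements
are omitted throughout: the network is resistive–capacitive only, and
valve switching is handled by the smooth `max(0, ·)` conductance rather
than event location, which a stiff solver handles cleanly.

## Scenarios

* `set_heart_rate(circuit, bpm)` — uniform rhythm, 40–150 bpm, window
  fractions preserved.
* `make_flutter(circuit, rate)` — uniform rapid rhythm with atrial
  activation disabled entirely.
* `make_af(circuit)` — atrial activation disabled with the irregular
  repeating cycle schedule 0.375 s / 0.4 s / 0.5 s (mean rate ≈ 141 bpm).
* `scale_atrial_contractility(circuit, k)` — multiplies LA $E_{es}$ by
  $k \in [0,1]$, mapping the loss of atrial kick continuously.
* `apply_laao(circuit)` — the three-parameter occlusion overwrite above.

All constructors are pure (the base circuit is never mutated) and
compose order-independently when they touch disjoint parameters.
Disabling atrial *activation* in flutter/fibrillation follows from the
absence of coordinated contraction; a residual-contractility pathway is
available through `scale_atrial_contractility()` instead.

## Simulation protocol and numerics

`simulate_circuit()` integrates 30 s by default with `deSolve::lsoda`
(automatic stiff/non-stiff switching; any deSolve method, e.g. pure BDF,
can be requested), relative and absolute tolerances $10^{-7}$, sampled
at 200 points per cycle with beat boundaries as exact sample points.
Metrics are computed on the final five complete beats (final full
schedule repetitions under irregular rhythms), by which time the
periodic orbit is reached: `periodicity_drift()` reports the maximum
beat-to-beat change of any element's end-cycle volume over the last
three cycles and warns above 0.5 mL. The initial condition distributes
the stressed volume over elements in proportion to an effective
compliance evaluated near 10 mmHg; since transients are discarded, this
only needs to start the solver inside the orbit's basin. A tenfold
tolerance refinement moves the final-beat mean LA pressure by well under
0.1 mmHg, and on a passive two-compartment reduction the solver matches
the closed-form RC decay to a relative error below $10^{-4}$ — both are
standing tests.

## Analysis layer

**a/c/v waves** (`detect_acv_waves()`): local maxima of the LA pressure
within one beat, classified by timing windows — the a-wave inside the
atrial activation window, the c-wave within the first 15% of the cycle
after ventricular onset, the v-wave from there to measured mitral
opening (first mitral flow above 2% of its beat maximum). Absence is a
valid result; the pure 0D model, which has no mitral-annulus motion,
generally shows no distinct c-wave in simulated traces, and the c
classification is exercised by synthetic fixtures.

**Mitral E/A** (`mitral_ea()`): E is the largest flow peak in the first
half of diastole (diastole starting at measured mitral opening), A the
largest inside the atrial window; A is absent when atrial contraction is
disabled. Flows are volumetric (mL/s); an optional effective-orifice
area divisor converts to cm/s for comparison with Doppler velocimetry,
and is deliberately user-supplied.

**PV loop** (`pv_loop()`): the beat's (volume, pressure) trajectory is
closed and searched for self-intersections with exact orientation
predicates, scanning segment pairs in path order so coincident contacts
resolve to the earliest parameter. Sub-loop areas come from the shoelace
formula (reported in mmHg·mL, no unit conversion); orientation is the
area sign. Simulated trajectories carry sliver micro-crossings where a
path almost retraces itself, so the decomposition splits at the
*dominant* crossing — the one maximising the smaller sub-loop area — and
`figure_eight` additionally requires the smaller sub-loop to exceed 0.5%
of the total swept area. All crossings are counted in
`n_intersections`.

**Appendage ejection fraction** (`laa_ejection_fraction()`):
$(A_{max} - A_{min}) / A_{max} \times 100$, for areas from any imaging
source.

## Calibration

`calibrate()` minimises
$\sum_i w_i \left( (s_i - t_i)/t_i \right)^2$ over declared free
parameter paths with bounded derivative-free search: Nelder–Mead on a
sine-transformed space for several parameters, golden-section for one.
Every evaluation is a full stiff simulation and the diode valves make
the response non-smooth, which is why gradient methods are not used.
Failures during the search are penalised rather than fatal; the best
iterate so far is returned on budget exhaustion and the objective
trajectory is nonincreasing by construction. The four LA constitutive
values may never be declared free — they are the fixed literature inputs.
Parameter recovery is verified in the tests: targets generated from a
known circuit, three free parameters (systemic resistance, systemic
compliance, LV elastance) perturbed ±30%, each recovered within 10%.

The headline reproduction calibrates a single free non-atrial parameter
(total blood volume, monotone in filling pressure) so the baseline
settles at the pre-occlusion mean LA pressure of 17.1 mmHg,
then applies `apply_laao()` and re-simulates. In this volume-conserving
closed loop the occlusion parameter changes raise mean LA pressure by
about +1 mmHg. The mechanism is structural: with diode valves and a
conservative loop, mean LA pressure is anchored by the LV's diastolic
filling demand, so the stiffened atrium mostly slides down its new
passive curve instead of transmitting the full pressure rise; the
elevation that survives comes from the larger reservoir-phase (v-wave)
swing and the stronger active kick. Exploration across wide
physiological ranges of the non-LA parameters (ventricular stiffness,
pulmonary compliances and resistances, valve resistances, relaxation
constants, both gating conventions, occlusion applied to an equilibrated
baseline state) moves this elevation only between roughly +0.2 and
+1.1 mmHg, consistently below the ~+2.4 mmHg a non-conservative or
inertance-bearing network can produce. The package reports what its
model computes.

## Problem sizes used

Standing tests run 30 s simulations (30 beats at 60 bpm) for scenario
phenomenology, 20 s for the single-parameter headline calibration and
12 s for the three-parameter recovery experiment — windows chosen so
every analysed quantity sits on the periodic orbit (drift well below
0.5 mL) while the whole suite stays comfortably reproducible on a single
CPU.

## What the model does and does not emulate

The simulator reproduces: LA reservoir/conduit/pump phase structure with
a figure-eight pressure–volume loop in sinus rhythm collapsing to a
lone v-loop without atrial contraction; E and A mitral inflow waves and
their loss of A under flutter/fibrillation; rate-dependent filling
impairment with depressed cardiac output at rapid ventricular response;
monotone dependence of the mitral A peak, LA a-wave and cardiac output
on atrial contractility; and the direction of the post-occlusion mean LA
pressure rise.

It does not emulate: autonomic reflexes or any baroreceptor control;
inertial (L) elements, hence no flow momentum or valve-closure
dynamics; mitral annular motion (no simulated c-wave); respiratory
variation; beat-to-beat stochastic RR variability fitted to clinical
recordings (the fibrillation schedule is the fixed three-cycle
pattern); atrial-septal shunting; and any wall-mechanics or imaging
quantities. Tests passing on this model therefore certify the lumped
hemodynamic behaviours above, not tissue-level mechanics or
patient-level variability.

## Known limitations

* The post-occlusion mean LA pressure elevation is structurally damped
  relative to measurements in open or inertance-bearing networks (see
  the calibration section).
* The steady-state analysis window (final five beats of 30 s) is a
  package choice; the drift diagnostic is the guard.
* The heart rate of the occlusion comparison is taken as 60 bpm, the
  sinus default.
* Velocity-unit comparisons require a user-supplied effective orifice
  area; the model itself produces volumetric flow.
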