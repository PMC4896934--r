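---
title: "A closed-loop cardiorespiratory model of graded aerobic exercise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A closed-loop cardiorespiratory model of graded aerobic exercise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(cardioresp)
```

`cardioresp` simulates the steady-state cardiorespiratory response of a
seated human to graded cycling, for a healthy subject and for a chronic
heart-failure (HF) patient.  It is a lumped-parameter model: the circulation
is a network of compliances, resistances and inertances; the lungs are one
mechanical compartment and one gas-exchanging compartment; and three
feedback controllers — the arterial baroreflex, local metabolic vascular
control, and the chemoreflex ventilation controller — close the loop.  This
vignette records the model structure, the assumptions behind it, and every
numerical or structural decision that was genuinely open.

## Circulation

Each ventricle follows a time-varying elastance: at end systole the pressure
is `Emax (V - V0)`, during filling it follows the exponential law
`a e^{bV} + c`.  The two laws are blended by an activation waveform
`phi(t) = sin^2(pi t / T_sys)` for `t < T_sys = 0.3 sqrt(TC)` seconds and 0
otherwise, so that the end-member laws are recovered exactly at `phi = 1`
and `phi = 0` and the blended pressure is continuous.  The half-sinusoid
shape and the `0.3 sqrt(TC)` systolic duration are standard
elastance-model practice; only the end-member laws are constrained by data.
Atria are passive compliances (no atrial kick).

The systemic side has two aortic segments (ascending/arch and
descending/abdominal, each with an inertance), five parallel peripheral
districts — upper body (fed from the ascending aorta), kidneys, splanchnic
region, and two legs (fed from the descending aorta) — and a venous return
through the superior vena cava (upper body) and the inferior vena cava,
split into a segment outside and a small segment inside the chest.  The
pulmonary circulation has arterial and venous compartments with an
inertance.  Heart valves and the leg venous valves are ideal diodes
(piecewise-exact, ties give zero flow); the integrator simply steps across
switching times.

Pressures are gauge (atmosphere = 0), so the tabulated absolute mean
pleural pressure of 754 mmHg becomes -6 mmHg.  Intrathoracic pressure is
added to every compliance inside the chest: both atria, both ventricles,
the ascending aorta, the superior vena cava, the inferior vena cava inside
the chest, and the pulmonary compartments.  Where the inferior vena cava
enters the chest a Starling resistor models the collapsible transition:
flow is ohmic while the downstream pressure exceeds the intrathoracic
pressure, flow-limited (vascular waterfall) when intrathoracic pressure
lies between upstream and downstream, and zero when the segment is
collapsed.

Two decisions here were open:

* **Total blood volume.**  The tables give unstressed volumes but not the
  total.  We set total volume to 70 ml per kg body weight (5320 ml at
  76 kg), the textbook norm, fill each compartment at a plausible resting
  pressure, and assign the residual to the splanchnic reservoir so the
  total is met exactly.  The initial distribution washes out during the
  rest stage; only the total matters at steady state.
* **Collapse branch of the district compliances.**  The leg muscle pump
  applies up to ~80 mmHg of external pressure to the leg compartments.  A
  linear compliance lets that pressure drive the stored volume negative — a
  linear law extrapolated far outside its calibration range.  Below the
  unstressed volume we therefore switch to a logarithmic branch,
  `P = (V0/C) log(V/V0)`, slope-matched to the linear branch at `V0`, so
  that emptying a compartment requires unboundedly negative transmural
  pressure, as collapsing vessels do.  The branch is inactive in every
  compartment except the legs during strong contractions.

The leg muscle pump itself is a pair of antiphase 1 Hz sinusoids (60 rpm
cycling) whose amplitude is proportional to workload; it acts as external
pressure on the leg compartments, and the leg venous valves rectify the
pumped flow.

## Respiratory mechanics and gas exchange

Pleural pressure is prescribed as a sinusoid about its mean with amplitude
`E TV / 2`; lung volume follows the single-compartment force balance
`Pm - Ppl = R dV/dt + E V`.  Tidal volume and frequency are updated only at
breath boundaries, taking the ventilation controller's latest output —
mid-breath retuning would create waveform discontinuities.

With the tabulated `R = 1 mmHg/(l/s)` and `E = 2 mmHg/l`, the airway time
constant is half a second, so at exercise breathing frequencies the lung
volume excursion is attenuated well below the commanded tidal volume
(by `E / sqrt(E^2 + w^2 R^2)` for angular breathing frequency `w` — an
exact property of the driven linear system that the test suite verifies).
The effective tidal volume, `TVeff = K_DV * TV`, is defined as the volume
reaching the alveoli per breath; we therefore scale the alveolar-ventilation
waveform (the lung-volume derivative) by the analytic factor that makes
each breath deliver exactly `TVeff` to the alveolar gas balance.  The
pleural waveform, and hence the intrathoracic pressure exported to the
circulation, is left untouched.  `K_DV` itself is the complement of the
dead-space fraction `-0.012 * peakVO2 + 0.611` (0.80 healthy, 0.57 HF).

Alveolar O2 and CO2 follow a mass balance on one well-mixed compartment:
the capacitance is the current alveolar gas volume plus the blood-side
storage `863 Vap dC/dP` of pulmonary blood equilibrating with the alveoli;
perfusion removes O2 into (and receives CO2 from) the non-shunted fraction
of pulmonary flow, which leaves exactly equilibrated with the alveolar
tensions (no diffusion limitation — the stated validity bound is
non-extreme exercise); inspiration adds fresh gas at the inspired tensions.
The factor 863 mmHg converts between BTPS alveolar volumes and STPD blood
contents.  Arterial blood is the shunt-weighted mixture of end-capillary
and mixed-venous blood (shunt fraction 0.02).

Dissociation curves are pinned in one module: a Hill O2 saturation
(n = 2.7, P50 = 26.6 mmHg, capacity 20.1 ml/dl, dissolved
0.003 ml/dl/mmHg) and a monotone power-law CO2 content calibrated to the
arterial and mixed-venous norms (40 mmHg -> 48 ml/dl, 46 -> 52).  Only
monotonicity, the physiological anchor points and the local slopes matter
to the closed loop; both inverses are exact (closed form for CO2, Newton
for O2).

Each tissue district holds gas in its own blood volume; tissue tension is
assumed equilibrated with venous blood.  Consumption follows the imposed
metabolic drive; production is consumption times the respiratory quotient.
Extraction is supply-limited by a quadratic roll-off (half-effect at
0.05 ml/dl) so that a district in oxygen debt cannot consume O2 that is
not there; anaerobic metabolism is outside the model's scope, and the
simulation reports an oxygen-debt diagnostic whenever the roll-off engages.
Mixed venous blood entering the lungs is tracked as a well-stirred pool
over the venae cavae, right heart and pulmonary artery; the arterial pool
spans the pulmonary veins, left heart and both aortic segments.  All blood
gas fluxes are upwind in the flow direction, so gas mass is conserved
exactly.

## Baroreflex with exercise resetting

The afferent input is the ascending-aorta elastic-recoil pressure (the
intrathoracic component removed), passed through a lead-lag filter
(`tau_p = 2.076 s`, `tau_z = 6.37 s`) and a logistic firing curve centred
on a set-point pressure that rises linearly with workload.  Efferent
sympathetic activity falls exponentially with afferent firing and gains a
linear workload offset; vagal activity interpolates logistically between a
lower limit (3.2 spikes/s) and a workload-lowered upper limit
(6.3 spikes/s at rest), minus a linear withdrawal term, clamped at zero.
Each effector (heart period, both contractilities, the five district
arterial resistances, the five venous unstressed volumes) applies
a static gain to the delayed efferent activity and relaxes to it through a
first-order block with its tabulated time constant; sympathetic delays are
2 s and the vagal delay 0.2 s (pure delays, ring-buffered at the 5 ms
control step).

Three reconstructions were required:

* **Sympathetic static function.**  The printed logarithmic form is not
  evaluable at the set point (logarithm of a negative number) and would
  violate the stated equilibrium property.  We use the standard
  log-compressive family
  `sf = C_H [log(Fes_d - Fes_inf + 1) - log(Fes_SET - Fes_inf + 1)]`,
  which is zero at the set point, monotone, and uses only housed symbols.
* **Vagal firing form.**  The tabulated values label 3.2 the *lower* and
  6.3 the *upper* limit of vagal activity, which matches the
  interpolating form `(Fev0 + Fev_inf e^w)/(1 + e^w)` (limits 3.2..6.3)
  and not a purely additive sigmoid (limits 3.2..9.5).  The interpolating
  form also reproduces the open-loop vagal-withdrawal heart-rate span
  (57-58 to ~85 bpm) that the additive form misses; the package's
  open-loop sweep test pins both single-channel spans.
* **Set-point activities.**  `Fes_SET` and `Fev_SET` are the rest
  (zero-workload) central values.  Defining them with the workload offsets
  included would zero every effector deviation at the operating point and
  abolish the exercise tachycardia entirely; with rest values, resetting
  moves the operating point away from the rest equilibrium, which is what
  produces the heart-rate and contractility rise.  The set-point
  equilibrium contract is enforced, and tested, at rest.

## Metabolic control and sympatholysis

Each district's venous O2 content drives a sigmoid static function centred
at half the reference content (the only reading under which the function is
~1 at the reference content, as the stated equilibrium requires), filtered
by a 2 s first-order block and scaled by the district gain.  Venous
resistances add the metabolic deviation directly.  Arterial resistances
combine both controllers with functional sympatholysis:

```
Ria = Ria_SET * S0 + [Ria_SET (1 - S0) + dRia_symp] * sf^10 + dRia_met
```

The tenth power (the only self-consistent reading of the printed gating
symbol) preserves the rest identity `1^10 = 1` and collapses sympathetic
vasoconstriction sharply once venous O2 falls below reference, as the
sympatholysis data require.  `S0 = 0.27` is the basal fraction remaining
when sympathetic tone is fully abolished.  Resistances and unstressed
volumes are floored (5% of basal, and zero, respectively); the floors never
engage with the shipped parameter sets.

## Exercise protocol and metabolic drive

Workload steps are instantaneous and drive four things at once: the
set-point resetting, the efferent workload offsets, the muscle-pump
amplitude, and the metabolic drive.  The drive is linear in workload:
healthy resting regions consume 196 ml/min (split 30/32/38% among upper
body, kidneys, splanchnic region) and each leg `5.87 WL + 20.23`; HF uses
`2.76 WL + 201.06` for resting regions and `3.83 WL + 28.87` per leg, with
respiratory quotients `0.859 + 0.0014 WL` and `0.877 + 0.006 WL`.

The default graded protocol is rest followed by 24.5, 49 and 73 W.  The
reference exercise-test protocol increments 24.5 W every 3 min; the
simulator, like the study it reproduces, is run to the periodic steady
state at each stage before summarizing, so the shipped protocol uses 300 s
stages — enough for the slowest state (splanchnic venous gas, time constant
~70 s) to settle — and summaries average the final 15 cardiac cycles.

## Numerics

Classical RK4 with a fixed 0.25 ms step advances the circulation, lung
volume and gas stores; controllers and delay lines update every 5 ms; the
simulation is bit-deterministic.  Halving the step changes stage summaries
by well under 1% (tested).  Blood volume is conserved to round-off because
every flow enters exactly two compartment derivatives.  State snapshots are
recorded every 10 ms and per cardiac cycle.  A full four-stage run
integrates 1200 simulated seconds in a few seconds of wall time.

Initialization: compartments at plausible resting pressures (splanchnic
absorbing the volume residual), gas tensions at arterial norms
(alveolar 100/40 mmHg), district venous contents at their reference values
(which are their expected rest steady states), controllers at set point.
The rest stage absorbs the remaining transient.

## Known limitations

* The printed steady-state exercise values for the healthy subject at 73 W
  (heart rate 134 bpm, cardiac output 10.2 l/min, TPR 0.5, MAP 134 mmHg)
  are mutually inconsistent (TPR x CO does not reproduce MAP - RAP) and
  the heart-rate figure is unreachable with the tabulated rest heart rate
  of 58 bpm: the vagal and sympathetic gains bound the reflex shortening
  of the heart period at about 0.51 s, capping heart rate near 114 bpm.
  The package keeps the tabulated parameters and reports what they
  produce (~103 bpm at 73 W, with cardiac output, leg flow, TPR and
  central a-v O2 difference displaced accordingly); the validation suite
  records these as failed comparisons rather than adjusting parameters.
* At 73 W the healthy legs approach complete O2 extraction, so the Fick
  closure between imposed uptake and delivered O2 opens to about 2.4% —
  the model's way of signalling oxygen debt, which (like anaerobic
  metabolism generally) is outside scope.
* No atrial contraction, pericardium, gravity or posture effects, no
  ventilation-perfusion mismatch, no pH/lactate buffering, no
  metabolite-specific vasodilation pathways.
* The chemoreflex has no explicit central/peripheral separation and no
  exercise feedforward drive; ventilation responds to arterial tensions
  only, updated breath by breath.
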