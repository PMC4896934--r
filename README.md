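# cardioresp

A closed-loop, lumped-parameter simulator of the human cardiorespiratory
response to graded cycling exercise, in health and in chronic heart
failure.

Exercise intolerance in heart failure emerges from the interaction of many
subsystems — a weakened ventricle, reset reflexes, blunted peripheral
vasodilation, inefficient ventilation — and no single measurement isolates
one of them. `cardioresp` couples the relevant mechanisms in one
deterministic model so that their interaction can be simulated, perturbed
and compared between a healthy subject and a heart-failure patient:

* a **time-varying elastance heart** (`P = phi·Emax(V−V0) +
  (1−phi)(a·e^{bV}+c)`) with passive atria and diode valves, in a
  twelve-compartment systemic + pulmonary network with a Starling resistor
  where the inferior vena cava enters the chest and a 1 Hz intramuscular
  **muscle pump** on the leg compartments;
* **respiratory mechanics** (`Pm − Ppl = R·dV/dt + E·V` driven by a
  sinusoidal pleural pressure of amplitude `E·TV/2`), exporting
  intrathoracic pressure to every compliance inside the chest;
* **alveolar and tissue gas exchange** with Hill O2 and power-law CO2
  dissociation curves, a 2% pulmonary shunt, and per-district venous gas
  stores (`d(C·V)/dt = C_a·Q_in − C_v·Q_out ∓ V̇O2`);
* an **arterial baroreflex with exercise resetting**: lead-lag afferent
  filter, logistic firing about a workload-shifted set point
  (`Paa_SET = Paa_SET0 + A·WL`), sympathetic stimulation and vagal
  withdrawal offsets, and delayed first-order effector channels for heart
  period, contractility, arterial resistances and venous unstressed
  volumes;
* **metabolic vasodilation with functional sympatholysis**:
  `Ria = Ria_SET·S0 + [Ria_SET(1−S0) + ΔRia_s]·sf^10 + ΔRia_met`, where
  the sigmoid `sf` is driven by district venous O2 content;
* a **chemoreflex ventilation controller**
  `Vent = (α·e^{β·PO2} + γ)(PCO2 − PCO2_tr)` with a linear
  frequency/tidal-volume split and a dead-space correction from the peak
  aerobic capacity.

The complete healthy and heart-failure parameter sets ship as plain-text
fixtures (`inst/extdata/*.params`); no external data are required.

## Worked example

```r
library(cardioresp)

sim <- simulate_exercise(graded_protocol(stage_s = 300, rest_s = 300),
                         condition = "healthy")
ss  <- steady_state_summary(sim)
round(ss[, c("watts","hr","map","co","qlla","tpr","avdo2_central","vent")], 2)
#> watts     hr   map   co qlla  tpr avdo2_central  vent
#>   0.0  60.51 81.45 4.28 0.33 1.08          5.52  5.43
#>  24.5  72.07 80.01 5.51 1.30 0.80          9.50 11.63
#>  49.0  86.06 85.54 6.76 1.94 0.69         12.01 17.71
#>  73.0 102.90 98.05 7.86 2.33 0.69         13.58 23.03
```

Each row is the mean over the final 15 cardiac cycles of one workload
stage: heart rate (bpm) rises as vagal withdrawal and sympathetic
stimulation shorten the heart period; cardiac output (l/min) and single-leg
flow (`qlla`, l/min) climb as the exercising legs vasodilate; total
peripheral resistance (`tpr`, mmHg·s/cm³) falls; the central arteriovenous
O2 content difference (ml/dl) widens as extraction deepens; and minute
ventilation (l/min) follows the CO2 load. Running the same protocol with
`condition = "hf"` shows the heart-failure phenotype: higher resting heart
rate and ventilation, smaller stroke volume, and a blunted rise in leg
perfusion.

Other entry points: `baroreflex_curve()` / `baroreflex_hr_span()` (open-loop
stimulus-response sweeps of the reflex, with single-channel isolation),
`metabolic_curve()` (resistance vs venous O2 content with or without
sympathetic tone), `fick_check()` (mass-balance audit), `tidy()`/`glance()`
and `autoplot()` on every result, and a thin command-line wrapper in
`inst/cli/cardioresp.R`. The methods vignette
(`vignettes/cardiorespiratory-exercise-model.Rmd`) documents the model,
its assumptions and the numerical choices.

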