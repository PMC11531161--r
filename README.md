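# fontansim

Closed-loop lumped-parameter (0D) simulation of the **failing Fontan
circulation supported by a continuous-flow systemic ventricular assist
device (VAD)**, for computational-physiology and cardiovascular-modelling
work.

A Fontan circulation has one functional ventricle and no subpulmonary pump:
systemic venous blood flows passively through the cavopulmonary connection
into the lungs. When it fails — through systolic or diastolic ventricular
dysfunction, atrioventricular valve regurgitation, or elevated pulmonary
vascular resistance — congestion of the systemic veins is the price of
maintaining pulmonary flow. This package models that circulation as a
six-compartment electrical analog and asks what a systemic VAD (ventricle →
aorta, in parallel with the aortic valve) does to cardiac index, arterial
pressure and central venous pressure in each pathophysiology, and how
stressed-blood-volume management changes the answer.

## The model

* **Chambers** (single atrium, single ventricle): time-varying elastance,
  blending a linear end-systolic relation `P_es = E_es (V − V0)` and an
  exponential end-diastolic relation `P_ed = A (e^{B(V−V0)} − 1)` with the
  raised-cosine activation `e(t) = 0.5 [1 − cos(π t / T_es)]` on
  `[0, 2 T_es)`; atrial activation leads by 16 ms.
* **Vascular beds**: modified three-element Windkessels (R_c, R_a, C_a,
  R_v, C_v) for the systemic and pulmonary circuits; `ΔP = QR`, `P = V/C`,
  `dV/dt = ΣQ_in − ΣQ_out`.
* **Valves**: ideal diodes with small series resistances; valve
  regurgitation as a reverse-connected diode-resistor branch.
* **CVP** is the exact divider pressure of the capacitor-free cavopulmonary
  node: `CVP = (P_Cap R_vs + P_Cvs R_cp) / (R_vs + R_cp)`.
* **Pump**: quadratic head–flow characteristic
  `ΔP = K_A r² + K_B r Q + K_C Q²`; in the closed loop the device runs at
  its zero-head operating point `Q0(r)` (see the methods vignette for why
  the reference operating states identify this coupling).
* **State**: the six stressed volumes; fixed-step RK4 at 0.2 ms conserves
  total stressed blood volume to round-off.

The study protocols are first-class functions: pump-speed ramps
(`ramp_rpm()`), ±100 mL stressed-volume titration with zero-crossing guards
(`titrate_sbv()`), the pulmonary-resistance sweep with 1 mL titration to a
near-zero mean atrial pressure (`sweep_pvri()`), and the CVP-tolerance
threshold (`cvp_vs_pvri_threshold()`).

## Worked example

```r
library(fontansim)

# a failing Fontan with systolic dysfunction (E_es 1.215 mmHg/mL, V_s 2036 mL)
sim <- run_to_steady_state(make_systolic_dysfunction())
glance(sim)
#>   cardiac_index mean_arterial_pressure   cvp mean_sa_pressure ...
#> 1          1.91                   65.0  20.0             14.3

# switch the VAD on at 3000 rpm: output and arterial pressure jump,
# venous congestion barely moves
assisted <- run_to_steady_state(set_pump_speed(make_systolic_dysfunction(),
                                               3000))
glance(assisted)
#>   cardiac_index mean_arterial_pressure   cvp mean_sa_pressure ...
#> 1          2.89                   87.8  19.7             11.0

# decongestion requires withdrawing stressed volume at full support
titrate_sbv(set_pump_speed(make_systolic_dysfunction(), 4000),
            step = 100, direction = "down")
#> <fontan_titration>
#>   V_s 1136 mL (delta -900 mL), stop: min-below-zero-guard
#>   CI 3.20 | MAP 86.4 | CVP 10.8 | SA 1.18 mmHg
```

The unassisted model idles at a cardiac index of 1.91 L/min/m² with a
central venous pressure of 20 mmHg — the congested pre-VAD state. Assist at
3000 rpm raises the index to 2.89 and the mean arterial pressure to
88 mmHg, but CVP only falls 0.3 mmHg: the pump moves blood, not congestion.
Withdrawing 900 mL of stressed volume at 4000 rpm brings CVP to 10.8 mmHg
while the pump holds the output at 3.2 L/min/m²; the titration stops when
the atrial pressure minimum would cross zero (mean atrial pressure
1.18 mmHg). `reproduce_table2()` and `reproduce_table3()` run the complete
scenario × speed grid and the PVRI sweep, attaching the bundled reference
values and delta columns; `sweep_pvri()` shows CVP climbing from 8.7 to
25.6 mmHg as PVRI rises from 3 to 9 Wood units m², crossing a 15 mmHg
tolerance between PVRI 5.1 and 6.0.

Scenario definitions can also be read from YAML
(`system.file("scenarios", ...)`, `load_scenario_config()`), and
`run_scenario()` writes a trajectory CSV, a summary JSON and a re-runnable
manifest per run. `autoplot()`, `plot_pv_loop()`, `plot_cvp_vs_pvri()` and
`plot_ci_vs_cvp()` give the standard displays.

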