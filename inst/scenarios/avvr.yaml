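# Atrioventricular valve regurgitation: reverse-connected diode-resistor
# branch of 0.225 mmHg s/mL across the AVV (regurgitant fraction ~51% without
# assist); pulmonary arterial resistance 0.06 mmHg s/mL (PVRI 3).
name: avvr
overrides:
  valves.R_AVVR: 0.225  # mmHg s/mL
  pulmonary.R_a: 0.06   # mmHg s/mL
stressed_blood_volume: 2015.0   # mL
rpm: 0.0
rpm_schedule: [3000.0, 3500.0, 4000.0]
protocol: ramp
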