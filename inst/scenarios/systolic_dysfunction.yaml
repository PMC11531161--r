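# Systolic ventricular dysfunction: ventricular end-systolic elastance reduced
# from 3 to 1.215 mmHg/mL; pulmonary arterial resistance 0.06 mmHg s/mL
# (PVRI 3 Wood units m^2); stressed blood volume calibrated so the unassisted
# circulation runs at cardiac index ~1.9 L/min/m^2 and CVP 20 mmHg.
name: systolic_dysfunction
overrides:
  sv.E_es: 1.215        # mmHg/mL
  pulmonary.R_a: 0.06   # mmHg s/mL
stressed_blood_volume: 2036.0   # mL
rpm: 0.0
rpm_schedule: [3000.0, 3500.0, 4000.0]
protocol: ramp
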