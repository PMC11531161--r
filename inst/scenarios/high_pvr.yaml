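# Elevated pulmonary vascular resistance: pulmonary arterial resistance raised
# from 0.03 to 0.23 mmHg s/mL (PVRI 8.39 Wood units m^2), baseline
# contractility; stressed blood volume calibrated to cardiac index
# ~1.9 L/min/m^2 and CVP 20 mmHg without assist.
name: high_pvr
overrides:
  pulmonary.R_a: 0.23   # mmHg s/mL
stressed_blood_volume: 1903.0   # mL
rpm: 0.0
rpm_schedule: [3000.0, 3500.0, 4000.0]
protocol: titrate_up
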