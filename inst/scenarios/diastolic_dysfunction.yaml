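# Diastolic ventricular dysfunction: ventricular EDPVR exponent raised from
# 0.033 to 0.0511 per mL (stiffer diastolic ventricle); pulmonary arterial
# resistance 0.06 mmHg s/mL (PVRI 3); stressed blood volume calibrated to
# cardiac index ~1.9 L/min/m^2 and CVP 20 mmHg without assist.
name: diastolic_dysfunction
overrides:
  sv.B: 0.0511          # 1/mL
  pulmonary.R_a: 0.06   # mmHg s/mL
stressed_blood_volume: 1999.0   # mL
rpm: 0.0
rpm_schedule: [3000.0, 3500.0, 4000.0]
protocol: ramp
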