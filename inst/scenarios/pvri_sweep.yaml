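# Base model of the pulmonary-resistance sweep: combined systolic and
# diastolic ventricular dysfunction under assist at 3500 rpm. The sweep
# raises pulmonary.R_a from 0.06 to 0.25 mmHg s/mL (PVRI 3 to 9) and titrates
# the stressed blood volume in 1 mL steps per point, so the volume here is a
# nominal starting value.
name: pvri_sweep
overrides:
  sv.E_es: 1.215        # mmHg/mL
  sv.B: 0.0511          # 1/mL
  pulmonary.R_a: 0.06   # mmHg s/mL
stressed_blood_volume: 1500.0   # mL
rpm: 3500.0
protocol: sweep
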