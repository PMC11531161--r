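# Reference pulmonary-resistance sweep of the combined systolic+diastolic
# dysfunction model under assist at 3500 rpm, stressed blood volume titrated
# per row to a mean atrial pressure just above zero. Used by
# reproduce_table3() to attach delta columns.
pvri_ref,R_ap,stressed_blood_volume_ref,cardiac_index_ref,mean_arterial_pressure_ref,cvp_ref,mean_sa_pressure_ref
3.01,0.060,910,2.80,74.9,8.70,0.260
3.96,0.090,1135,2.80,77.5,11.4,0.263
5.07,0.125,1397,2.80,80.6,14.5,0.262
6.02,0.155,1621,2.80,83.3,17.1,0.256
6.97,0.185,1846,2.80,86.0,19.8,0.260
8.08,0.220,2108,2.80,89.1,22.9,0.259
9.03,0.250,2332,2.80,91.7,25.6,0.253
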