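# Reference steady-state hemodynamics of the four failing-Fontan scenarios,
# as reported for the source parameterization of this model (scenario overrides
# applied to the standard parameter set). Used by reproduce_table2() to attach
# delta columns. Volumes mL, pressures mmHg, cardiac index L/min/m^2, RF %.
scenario,condition,stressed_blood_volume_ref,cardiac_index_ref,mean_arterial_pressure_ref,cvp_ref,mean_sa_pressure_ref,regurgitant_fraction_ref
systolic,baseline,2036,1.91,65.0,20.0,14.3,NA
systolic,rpm3000,2036,2.89,87.8,19.7,11.0,NA
systolic,rpm3500,2036,3.05,91.7,19.7,10.5,NA
systolic,rpm4000,2036,3.23,95.7,19.6,9.92,NA
systolic,rpm4000_titrated,1136,3.20,86.4,10.8,1.18,NA
diastolic,baseline,1999,1.90,65.0,20.0,14.3,NA
diastolic,rpm3000,1999,3.13,93.5,19.7,10.2,NA
diastolic,rpm3500,1999,3.33,98.1,19.6,9.58,NA
diastolic,rpm4000,1999,3.53,102.7,19.5,8.93,NA
diastolic,rpm4000_titrated,1199,3.20,87.1,11.5,1.82,NA
avvr,baseline,2015,1.90,65.0,20.0,14.3,50.9
avvr,rpm3000,2015,3.00,90.4,19.7,10.7,41.1
avvr,rpm3500,2015,3.18,94.8,19.7,10.1,39.6
avvr,rpm4000,2015,3.37,99.2,19.6,9.51,38.0
avvr,rpm4000_titrated,1115,3.20,86.3,10.6,1.00,2.00
high_pvr,baseline,1903,1.91,65.0,20.0,4.01,NA
high_pvr,rpm3000,1903,2.40,77.4,20.7,0.506,NA
high_pvr,rpm3500,2203,2.80,90.1,24.0,0.445,NA
high_pvr,rpm4000,2503,3.20,102.9,27.3,0.382,NA
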