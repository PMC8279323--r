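patient_id,timepoint,systolic_velocity_cm_s,diastolic_velocity_cm_s,wbv_cP,bp_systolic_mmHg,bp_diastolic_mmHg,pulse_bpm,vein_area_cm2,vein_diameter_cm,reynolds,arch_angle_deg
P93,3mo,17.6,9.4,4.12,134,84,83,0.513,0.81,367,145
P93,12mo,17.6,5.7,3.96,119,81,71,0.337,0.66,311,113
P96,3mo,66.6,38.3,2.96,174,96,101,0.347,0.66,1574,133
P96,12mo,43.5,21,4.08,122,70,81,0.337,0.66,746,132
P98,3mo,49.7,38.2,3.2,130,76,90,0.532,0.82,1350,130
P98,12mo,17.6,8.23,3.86,143,82,79,0.840,1.03,498,115
P104,3mo,39.6,29.2,2.68,124,80,81,0.930,1.1,1723,125
P104,12mo,9.4,4.6,4.63,125,81,84,0.594,0.9,194,115
P122,3mo,52.5,24.3,3.96,99,60,88,0.559,0.84,1180,150
P122,12mo,56.6,41.2,3.35,130,74,88,0.935,1.09,1952,152
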