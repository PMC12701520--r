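subject_id,status,age_mri,sex,education,icv,ah_left,ah_right,ph_left,ph_right,hv_left_total,hv_right_total,amyloid_suvr,tracer
S0001,CI,74.5,F,16,1450000,1700,1650,1400,1350,3100,3000,1.25,florbetapir
S0002,CU,68.2,M,18,1520000,1850,1840,1500,1490,3350,3330,0.98,florbetapir
S0003,CI,81.0,F,12,1380000,1300,1420,1050,1180,2350,2600,1.15,florbetaben
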