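site_id,site_type,visit_probability,medicare_missing_rate,name_typo_rate,nickname_rate,dob_transpose_rate,partial_dob_rate
clinic1,clinic,0.20,0.026,0.01,0.02,0.002,0.005
clinic2,clinic,0.25,0.049,0.01,0.02,0.002,0.005
clinic3,clinic,0.15,0.009,0.01,0.02,0.002,0.005
clinic4,clinic,0.25,0.034,0.01,0.02,0.002,0.005
clinic5,clinic,0.10,0.009,0.01,0.02,0.002,0.005
clinic6,clinic,0.10,0.070,0.01,0.02,0.002,0.005
clinic7_sexual_health,clinic,0.20,0.540,0.02,0.03,0.002,0.010
lab1_public,laboratory,0.45,0.100,0.01,0.01,0.002,0.005
lab2_public,laboratory,0.15,0.974,0.01,0.01,0.002,0.005
lab3_private,laboratory,0.10,0.480,0.01,0.01,0.002,0.005
lab4_private,laboratory,0.30,0.040,0.01,0.01,0.002,0.005
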