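patient_id,age,sex,height,weight,population,creatinine,cystatin_c,flags,measured_gfr
p1,40,female,165,68,,80,1.2,,
p2,70,male,176,58,,45,2.4,MUSCLE_MASS_LOW,
p3,55,female,162,70,,70,2.0,GLUCOCORTICOID_MODERATE_HIGH_DOSE,
p4,62,male,180,84,,95,1.0,,
p5,48,male,178,79,,60,2.2,,
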