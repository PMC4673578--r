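- equation_id: grubb_cystatin
  marker_basis: cystatin_c
  form: power_law_cystatin
  params:
    A: 84.69
    B: 1.68
    pediatric_multiplier: 1.384
    pediatric_cutoff: 14.0
  age_range:
  - 1.0
  - 120.0
  required_fields:
  - age
  - cystatin_c
- equation_id: mdrd_idms
  marker_basis: creatinine
  form: mdrd_like
  params:
    c0: 175.0
    e1: -1.154
    e2: -0.203
    female_coeff: 0.742
    pop_black: 1.212
  age_range:
  - 18.0
  - 120.0
  required_fields:
  - age
  - sex
  - creatinine
- equation_id: mdrd_japanese
  marker_basis: creatinine
  form: mdrd_like
  params:
    c0: 175.0
    e1: -1.154
    e2: -0.203
    female_coeff: 0.742
    pop_japanese: 0.763
  age_range:
  - 18.0
  - 120.0
  required_fields:
  - age
  - sex
  - creatinine
- equation_id: counahan_barratt
  marker_basis: creatinine
  form: height_over_creatinine
  params:
    k: 0.43
  age_range:
  - 1.0
  - 18.0
  required_fields:
  - age
  - height
  - creatinine
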