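name: repaglinide
mol_weight: 452.58999999999997
fu_plasma: 0.014999999999999999
blood_plasma_ratio: 0.62
ka: 2.5
fa: 1
lag_time: 0.10000000000000001
fg_model:
  type: fixed_fg
  fg: 1
vss: 0.41999999999999998
v_sac: 0
q_sac: 0
enzyme_clearances:
  CYP2C8:
    value: 13
    units: uL/min/pmol
  CYP3A4_liver:
    value: 1.0600000000000001
    units: uL/min/pmol
  HLM_additional:
    value: 46.799999999999997
    units: uL/min/mg
cl_renal: 0.25
cl_biliary: 0
cl_additional: 0
interactions: []
provenance: CYP2C8 probe substrate with CYP2C8/CYP3A4 metabolic split ~0.61/0.29;
  literature-informed PK, 0.25 mg single dose.

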