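name: omeprazole
mol_weight: 345.42000000000002
fu_plasma: 0.050000000000000003
blood_plasma_ratio: 0.58999999999999997
ka: 3
fa: 1
lag_time: 0.29999999999999999
fg_model:
  type: fixed_fg
  fg: 1
vss: 0.29999999999999999
v_sac: 0
q_sac: 0
enzyme_clearances:
  CYP2C19:
    value: 11.9
    units: uL/min/pmol
  CYP3A4_liver:
    value: 0.187
    units: uL/min/pmol
  HLM_additional:
    value: 3.9300000000000002
    units: uL/min/mg
cl_renal: 0.10000000000000001
cl_biliary: 0
cl_additional: 0
interactions: []
provenance: CYP2C19 probe substrate (fm_CYP2C19 ~0.85, minor CYP3A4); literature-informed
  PK, CL/F ~39 L/h, 20 mg single dose.

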