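name: metoprolol
mol_weight: 267.36000000000001
fu_plasma: 0.88
blood_plasma_ratio: 1.1200000000000001
ka: 2
fa: 1
lag_time: 0.20000000000000001
fg_model:
  type: fixed_fg
  fg: 1
vss: 3.2000000000000002
v_sac: 0
q_sac: 0
enzyme_clearances:
  CYP2D6:
    value: 2.6299999999999999
    units: uL/min/pmol
  HLM_additional:
    value: 5.4000000000000004
    units: uL/min/mg
cl_renal: 2
cl_biliary: 0
cl_additional: 0
interactions: []
provenance: CYP2D6 probe substrate (fm_CYP2D6 ~0.78); literature-informed PK (low
  binding, large V), 100 mg single dose.

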