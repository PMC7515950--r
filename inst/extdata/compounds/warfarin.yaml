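name: warfarin
mol_weight: 308.32999999999998
fu_plasma: 0.01
blood_plasma_ratio: 0.55000000000000004
ka: 1.2
fa: 1
lag_time: 0.20000000000000001
fg_model:
  type: fixed_fg
  fg: 1
vss: 0.14000000000000001
v_sac: 0
q_sac: 0
enzyme_clearances:
  CYP2C9:
    value: 0.089999999999999997
    units: uL/min/pmol
cl_renal: 0.028000000000000001
cl_biliary: 0
cl_additional: 0
interactions: []
provenance: 'CYP2C9 probe substrate (S-warfarin-like: fm_CYP2C9 ~0.9, low CL ~0.17
  L/h, V ~10 L, very high protein binding); 15 mg single dose.'

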