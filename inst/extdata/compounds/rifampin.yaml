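name: rifampin
mol_weight: 822.94000000000005
fu_plasma: 0.14999999999999999
blood_plasma_ratio: 0.90000000000000002
ka: 1.2
fa: 1
lag_time: 0.29999999999999999
fg_model:
  type: fixed_fg
  fg: 1
vss: 0.45000000000000001
v_sac: 0
q_sac: 0
enzyme_clearances:
  HLM_additional:
    value: 18
    units: uL/min/mg
cl_renal: 1.5
cl_biliary: 0
cl_additional: 0
interactions:
  CYP3A4_liver:
    ki_reversible: ~
    kinact: ~
    ki_app: ~
    ind_max: 16
    ind_c50: 0.32000000000000001
    provenance: strong CYP3A4 induction (IndMax/IndC50 in the range of published PBPK
      values; midazolam AUC ratio ~0.16 at 600 mg QD)
  CYP3A4_gut:
    ki_reversible: ~
    kinact: ~
    ki_app: ~
    ind_max: 16
    ind_c50: 0.32000000000000001
    provenance: same constants applied to the enterocyte pool
provenance: Literature-informed rifamycin PK; strong CYP3A4 inducer exemplar (600
  mg QD).

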