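name: itraconazole
mol_weight: 705.63
fu_plasma: 0.035999999999999997
blood_plasma_ratio: 0.57999999999999996
ka: 0.5
fa: 1
lag_time: 0.29999999999999999
fg_model:
  type: fixed_fg
  fg: 1
vss: 6
v_sac: 0
q_sac: 0
enzyme_clearances:
  HLM_additional:
    value: 120
    units: uL/min/mg
cl_renal: 0
cl_biliary: 0
cl_additional: 0
interactions:
  CYP3A4_liver:
    ki_reversible: 0.0040000000000000001
    kinact: ~
    ki_app: ~
    ind_max: ~
    ind_c50: ~
    provenance: 'calibrated to the strong class: midazolam AUC ratio ~5.8 at 200 mg
      QD'
  CYP3A4_gut:
    ki_reversible: 0.0040000000000000001
    kinact: ~
    ki_app: ~
    ind_max: ~
    ind_c50: ~
    provenance: same constant applied to the enterocyte pool
provenance: Literature-informed triazole PK (high Vss, long half-life, very low unbound
  Ki on CYP3A4); strong-class CYP3A4 inhibitor exemplar (200 mg QD).

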