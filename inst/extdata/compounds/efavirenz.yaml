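name: efavirenz
mol_weight: 315.67000000000002
fu_plasma: 0.0060000000000000001
blood_plasma_ratio: 0.73999999999999999
ka: 0.59999999999999998
fa: 1
lag_time: 0.5
fg_model:
  type: fixed_fg
  fg: 1
vss: 3.5
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
    ki_reversible: ~
    kinact: ~
    ki_app: ~
    ind_max: 1.8
    ind_c50: 0.01
    provenance: CYP3A4 induction calibrated to the moderate-inducer class (fedratinib
      single-dose AUC ratio ~0.3-0.4 at 600 mg QD)
  CYP3A4_gut:
    ki_reversible: ~
    kinact: ~
    ki_app: ~
    ind_max: 1.8
    ind_c50: 0.01
    provenance: same constants applied to the enterocyte pool
provenance: Literature-informed NNRTI PK (very high protein binding); moderate CYP3A4
  inducer (600 mg QD).

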