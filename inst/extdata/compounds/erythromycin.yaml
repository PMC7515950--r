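name: erythromycin
mol_weight: 733.92999999999995
fu_plasma: 0.29999999999999999
blood_plasma_ratio: 0.90000000000000002
ka: 1
fa: 0.5
lag_time: 0.29999999999999999
fg_model:
  type: fixed_fg
  fg: 1
vss: 0.55000000000000004
v_sac: 0
q_sac: 0
enzyme_clearances:
  HLM_additional:
    value: 25
    units: uL/min/mg
cl_renal: 7
cl_biliary: 0
cl_additional: 0
interactions:
  CYP3A4_liver:
    ki_reversible: ~
    kinact: 1.1499999999999999
    ki_app: 15
    ind_max: ~
    ind_c50: ~
    provenance: mechanism-based inactivation, calibrated to the moderate class (midazolam
      AUC ratio ~2.1 at 500 mg BID)
  CYP3A4_gut:
    ki_reversible: ~
    kinact: 1.1499999999999999
    ki_app: 15
    ind_max: ~
    ind_c50: ~
    provenance: same constants applied to the enterocyte pool
provenance: Literature-informed macrolide PK; time-dependent CYP3A4 inhibitor of the
  moderate class (500 mg BID).

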