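name: diltiazem
mol_weight: 414.51999999999998
fu_plasma: 0.22
blood_plasma_ratio: 1
ka: 1.5
fa: 0.90000000000000002
lag_time: 0.20000000000000001
fg_model:
  type: fixed_fg
  fg: 0.90000000000000002
vss: 4
v_sac: 0
q_sac: 0
enzyme_clearances:
  HLM_additional:
    value: 50
    units: uL/min/mg
cl_renal: 0
cl_biliary: 0
cl_additional: 0
interactions:
  CYP3A4_liver:
    ki_reversible: ~
    kinact: 0.45000000000000001
    ki_app: 2.2000000000000002
    ind_max: ~
    ind_c50: ~
    provenance: mechanism-based inactivation, calibrated to the moderate class (midazolam
      AUC ratio ~2.2 at 120 mg BID)
  CYP3A4_gut:
    ki_reversible: ~
    kinact: 0.45000000000000001
    ki_app: 2.2000000000000002
    ind_max: ~
    ind_c50: ~
    provenance: same constants applied to the enterocyte pool
provenance: Literature-informed benzothiazepine PK; time-dependent CYP3A4 inhibitor
  of the moderate class (120 mg BID).

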