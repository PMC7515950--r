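name: fluconazole
mol_weight: 306.26999999999998
fu_plasma: 0.89000000000000001
blood_plasma_ratio: 1
ka: 1.5
fa: 1
lag_time: 0.20000000000000001
fg_model:
  type: fixed_fg
  fg: 1
vss: 0.75
v_sac: 0
q_sac: 0
enzyme_clearances:
  HLM_additional:
    value: 0.10000000000000001
    units: uL/min/mg
cl_renal: 0.90000000000000002
cl_biliary: 0
cl_additional: 0
interactions:
  CYP3A4_liver:
    ki_reversible: 5
    kinact: ~
    ki_app: ~
    ind_max: ~
    ind_c50: ~
    provenance: moderate reversible CYP3A4 inhibition (unbound Ki, calibrated)
  CYP3A4_gut:
    ki_reversible: 5
    kinact: ~
    ki_app: ~
    ind_max: ~
    ind_c50: ~
    provenance: same constant applied to the enterocyte pool
  CYP2C19:
    ki_reversible: 1
    kinact: ~
    ki_app: ~
    ind_max: ~
    ind_c50: ~
    provenance: dual CYP2C19 inhibition; with the CYP3A4 entry gives a fedratinib
      single-dose AUC ratio ~4.4 at 400 mg QD
provenance: Literature-informed triazole PK (renally cleared, low protein binding,
  long half-life); dual CYP2C19/CYP3A4 inhibitor (400 mg QD).

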