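name: ketoconazole
mol_weight: 531.42999999999995
fu_plasma: 0.029000000000000001
blood_plasma_ratio: 0.62
ka: 1.2
fa: 1
lag_time: 0.20000000000000001
fg_model:
  type: fixed_fg
  fg: 1
vss: 0.34000000000000002
v_sac: 0
q_sac: 0
enzyme_clearances:
  HLM_additional:
    value: 40
    units: uL/min/mg
cl_renal: 0.20000000000000001
cl_biliary: 0
cl_additional: 0
interactions:
  CYP3A4_liver:
    ki_reversible: 0.1106
    kinact: ~
    ki_app: ~
    ind_max: ~
    ind_c50: ~
    provenance: 'calibrated: reversible unbound Ki reproducing the clinical/model
      fedratinib 300 mg single-dose interaction (AUC ratio ~3.17, Cmax ratio ~2.09);
      with this value the model''s midazolam index effect (~2.9x) sits below the regulatory
      strong threshold - see package vignette'
  CYP3A4_gut:
    ki_reversible: 0.1106
    kinact: ~
    ki_app: ~
    ind_max: ~
    ind_c50: ~
    provenance: same constant applied to the enterocyte pool
provenance: Literature-informed azole antifungal PK (fu ~0.03, B/P ~0.6, CL/F ~7 L/h,
  V ~25 L, tmax ~2 h); potent reversible CYP3A4/5 inhibitor, no TDI. Interaction constant
  calibrated against the fedratinib DDI study design (200 mg BID).

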