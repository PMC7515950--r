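name: midazolam
mol_weight: 325.76999999999998
fu_plasma: 0.032000000000000001
blood_plasma_ratio: 0.66000000000000003
ka: 3
fa: 1
lag_time: 0.10000000000000001
fg_model:
  type: gut_extraction
  clint_gut:
    value: 0.51039999999999996
    units: uL/min/pmol
  fu_gut: 1
vss: 0.90000000000000002
v_sac: 0.40000000000000002
q_sac: 20
enzyme_clearances:
  CYP3A4_liver:
    value: 4
    units: uL/min/pmol
  HLM_additional:
    value: 48
    units: uL/min/mg
cl_renal: 0.070000000000000007
cl_biliary: 0
cl_additional: 0
interactions: []
provenance: Sensitive CYP3A4 index substrate; hepatic fm_CYP3A4 ~0.90 with enterocyte
  CYP3A4 extraction. Oral CL/F ~85 L/h; hepatic/gut split calibrated so the fedratinib
  500 mg QD cocktail interaction reproduces AUC ratio ~4.26 and Cmax ratio ~2.0.

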