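name: fedratinib
mol_weight: 524.67999999999995
fu_plasma: 0.050000000000000003
blood_plasma_ratio: 1
ka: 0.80000000000000004
fa: 1
lag_time: 0.25
fg_model:
  type: gut_extraction
  clint_gut:
    value: 12.917999999999999
    units: uL/min/pmol
  fu_gut: 1
vss: 2.5979999999999999
v_sac: 6
q_sac: 2.528
enzyme_clearances:
  CYP3A4_liver:
    value: 0.58959973052948611
    units: uL/min/pmol
  CYP2C19:
    value: 1.0255057706356387
    units: uL/min/pmol
  CYP2D6:
    value: 0.21982170553888847
    units: uL/min/pmol
  HLM_additional:
    value: 0
    units: uL/min/mg
cl_renal: 1.9842884147519075
cl_biliary: 1.2627289912057602
cl_additional: 0
interactions:
  CYP3A4_liver:
    ki_reversible: ~
    kinact: 1.4832000000000001
    ki_app: 1.5
    ind_max: 4
    ind_c50: 2
    provenance: 'calibrated: net time-dependent inactivation + induction chosen so
      steady-state hepatic CYP3A4 flux share falls to ~34% under 400 mg QD and the
      AUC accumulation ratio is ~2.5'
  CYP3A4_gut:
    ki_reversible: 5
    kinact: 0.15939999999999999
    ki_app: 1.5
    ind_max: 4
    ind_c50: 2
    provenance: 'calibrated: enterocyte CYP3A4 interaction set so the single-dose
      ketoconazole Cmax ratio (~2.1) and the steady-state strong-inhibitor AUC ratio
      (~2) are reproduced'
  CYP2C8:
    ki_reversible: 1.1112
    kinact: ~
    ki_app: ~
    ind_max: ~
    ind_c50: ~
    provenance: calibrated to the predicted repaglinide AUC ratio (~1.46)
  CYP2C9:
    ki_reversible: 50
    kinact: ~
    ki_app: ~
    ind_max: ~
    ind_c50: ~
    provenance: weak in vitro CYP2C9 inhibition; yields a null warfarin interaction
  CYP2C19:
    ki_reversible: 0.95830000000000004
    kinact: ~
    ki_app: ~
    ind_max: ~
    ind_c50: ~
    provenance: calibrated to the predicted omeprazole AUC ratio (~1.46)
  CYP2D6:
    ki_reversible: 1.3123
    kinact: ~
    ki_app: ~
    ind_max: ~
    ind_c50: ~
    provenance: calibrated to the predicted metoprolol AUC ratio (~1.15)
provenance: 'Calibrated victim/perpetrator model of fedratinib. Absorption/distribution
  (ka, Vss, Vsac, Q) and per-enzyme intrinsic clearances set by the retrograde middle-out
  procedure against: dose-normalized AUCinf 28.5 ng.h/mL/mg (300 mg single dose, healthy),
  day-1 fm/fe split 64/16/2/11/7 (CYP3A4/CYP2C19/CYP2D6/renal/biliary), single-dose
  Cmax ~529 ng/mL at 300 mg.'

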