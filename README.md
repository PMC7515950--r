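# pbpkddi

Minimal physiologically based pharmacokinetic (PBPK) simulation of metabolic
drug–drug interactions (DDIs), with dynamic enzyme turnover.

## The problem

Fedratinib, an oral JAK2 inhibitor dosed 400 mg once daily (QD), is cleared
mostly by CYP3A4 with contributions from CYP2C19, CYP2D6 and renal/biliary
excretion — and it simultaneously *inhibits* (reversibly and
time-dependently) and *induces* CYP3A4, including its own metabolism. The
clinically important questions — how much does a strong CYP3A4 inhibitor like
ketoconazole raise fedratinib exposure, how much does fedratinib raise the
exposure of CYP3A4/2C8/2C9 substrates, and what dose adjustment does that
imply — cannot be answered by static equations, because the active CYP3A4
pool changes over days of dosing.

`pbpkddi` is a self-contained R implementation of the mechanistic workflow
used for such assessments:

* a **minimal PBPK model** per drug: gut lumen → enterocyte (dynamic gut
  CYP3A4 extraction) → well-stirred liver → central + single adjusting
  peripheral compartment, with per-enzyme intrinsic clearances and renal /
  biliary / additional systemic pathways;
* **enzyme turnover** per pool `E(t)` (baseline 1):

  `dE/dt = kdeg · [1 + Ind_max · I_u / (Ind_C50 + I_u)] − E · [kdeg + k_inact · I_u / (K_I + I_u)]`

  with reversible inhibition scaling each intrinsic clearance by
  `1 / (1 + Σ I_u / K_i)`; unbound liver-inlet concentration drives hepatic
  terms, enterocyte concentration drives the gut pool — so auto-inhibition
  and auto-induction fall out of the same equations as cross-compound
  effects;
* **retrograde ("middle-out") calibration**: per-enzyme intrinsic clearances
  are back-calculated from a target dose-normalized AUC and a target
  fraction-of-elimination (fm/fe) split, rather than scaled up from in vitro
  rates;
* **virtual-trial simulation**: log-normally sampled subject physiology
  (CYP abundances, liver size, flows, binding), paired treatment arms on
  identical subjects, geometric-mean exposure ratios with 90% CIs,
  parameter-sensitivity sweeps, a dose re-escalation scenario engine, and a
  label-logic helper (`recommend_dose()`);
* a **synthetic concentration–time data generator** so the calibration and
  verification stages are fully testable without clinical data.

The ODE right-hand side is compiled C (via `deSolve`'s compiled-model
interface); a full 28-day virtual subject simulates in ~10 ms.

## Worked example

Calibrate fedratinib from its exposure / fm targets, then reproduce the
ketoconazole interaction study:

```r
library(pbpkddi)

sub <- central_subject()
lib <- compound_library()                       # 13 fixtures, YAML-backed
lib$fedratinib <- retrograde_clint(fedratinib_target(), sub,
                                   fedratinib_shell())

# day-1 and steady-state elimination split under 400 mg QD
sim <- simulate_pk(sub, lib$fedratinib, regimen("fedratinib", 400, "qd", 0, 672), 672)
round(100 * fm_fe_partition(sim, c(0, 24)))      # day 1
#> CYP3A4_liver  CYP2C19  CYP2D6  renal  biliary
#>           64       16       2     11        7
round(100 * fm_fe_partition(sim, c(648, 672)))   # steady state
#> CYP3A4_liver  CYP2C19  CYP2D6  renal  biliary
#>           34       28       4     21       13

# paired virtual trials: fedratinib 300 mg single dose +/- ketoconazole 200 mg BID
ddi <- run_trials(ddi_study("ketoconazole_single", seed = 1), lib)
ddi
#> <ddi_result> victim fedratinib + ketoconazole, 10 trials x 10 subjects, metric auc_inf
#>   GM auc ratio 3.143 (90% CI 3.017-3.274)
#>   GM cmax ratio 2.124 (90% CI 2.064-2.186)

recommend_dose(2.07)   # steady-state strong-inhibitor magnitude
#>   auc_ratio recommended_dose_mg rationale
#>        2.07                 200 steady-state AUC ratio 2.07 >= 2 ...
```

The day-1 split reads: on the first 400 mg dose, 64% of systemic elimination
proceeds through hepatic CYP3A4. By steady state the share has fallen to 34%
— the net effect of fedratinib inactivating and inducing its own CYP3A4 —
which is why repeated-dose interactions with CYP3A4 inhibitors are roughly
half the single-dose magnitude (AUC ratio ~2 instead of ~3.2).

`tidy()`, `glance()` and `autoplot()` methods are provided for simulations
and DDI results; `plot_enzymes()` shows the active-enzyme trajectories.

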