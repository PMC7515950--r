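---
title: "Methods: a minimal PBPK model for metabolic DDI simulation with enzyme turnover"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a minimal PBPK model for metabolic DDI simulation with enzyme turnover}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its model, its calibration
procedure, the choices made where the design was genuinely open, and the
limits of what the test suite demonstrates.

## 1. The model

### States

For each compound the engine tracks a gut lumen amount, a central amount, a
peripheral ("single adjusting compartment") amount, and cumulative
eliminated mass per pathway. Seven enzyme pools are shared across compounds:
hepatic CYP3A4, enterocyte (gut) CYP3A4, CYP2C19, CYP2D6, CYP2C8, CYP2C9 and
a lumped additional hepatic microsomal activity (`HLM_additional`). Each
pool carries one state, its active fraction \(E(t)\) relative to baseline.

### Absorption and gut extraction

Oral doses are event-based additions of `fa * dose` to the lumen (after the
absorption lag); absorption is first order (`ka`). The absorbed flux passes
an enterocyte CYP3A4 extraction step,
\[
f_g(t) \;=\; \frac{Q_{ent}}{Q_{ent} + f_{u,gut}\,CL_{int,gut}\,E_{gut}(t)\,/\,(1+\textstyle\sum_c I_{ent,c}/K_{i,c})},
\]
the flow-limited ("Q-gut"-style) form with villous blood flow
\(Q_{ent}\) (default 18 L/h) and enterocyte inhibitor concentration
\(I_{ent,c} = f_{u,gut}\,k_a A_{gut}/Q_{ent}\). Compounds without a gut
pathway declare a fixed \(f_g\). Mass extracted in the gut wall is
accounted as a pre-systemic pathway and **excluded** from the fm/fe
partition, which is defined on systemic clearance (see §3).

### Liver and distribution

The liver is well-stirred: with unbound fraction in blood
\(f_{uB} = f_u/BP\) and the inhibited, turnover-scaled per-enzyme intrinsic
clearances \(CL_{int,e}(t) = CL_{int,e}\,E_e(t)/(1+\sum_c I_{u,c}/K_{i,c,e})\),
hepatic extraction is \(E_h = S/(Q_h + S)\), \(S = f_{uB}\sum_e CL_{int,e}(t)\).
The liver-inlet blood concentration (systemic + portal absorption flux,
\(C_{in} = C_{cen,B} + \text{flux}_{portal}/Q_h\)) drives both elimination and
every hepatic interaction term, so first-pass extraction and inlet-spike
inhibition emerge without extra machinery. Hepatic elimination flux is split
across enzymes in proportion to their current effective intrinsic
clearances. Renal, biliary and additional systemic clearances act linearly
on central plasma concentration; biliary clearance is a bookkeeping pathway
(no enterohepatic recirculation). Distribution is central volume `vss`
(L/kg) plus one peripheral compartment (`v_sac` L/kg, flow `q_sac` L/h) —
the minimal structure that supports multi-exponential disposition.

### Enzyme turnover

Each pool follows
\[
\frac{dE}{dt} = k_{deg}\Big[1 + \frac{Ind_{max} I_u}{Ind_{C50}+I_u}\Big]
 - E\Big[k_{deg} + \frac{k_{inact} I_u}{K_{I}+I_u}\Big],\qquad E(0)=1,
\]
the standard dynamic net-effect form combining synthesis induction and
mechanism-based inactivation; unbound liver-inlet (hepatic pools) or
enterocyte (gut pool) concentrations drive the terms, summed over all
compounds present — auto-inhibition/induction is therefore the same
mechanism as cross-compound interaction. Degradation rates default to
`kdeg = 0.0193/h` for hepatic pools (≈36 h half-life) and `0.03/h` for
enterocyte CYP3A4 (≈23 h), widely used turnover values; they are exposed as
an argument of `simulate_pk()` because the recovery timescale after
inhibitor washout is exactly `kdeg` (verified against the exponential closed
form in the tests).

### Numerics

`lsoda` (stiff-capable) at `rtol 1e-8`, `atol 1e-10`; dosing by solver
events with no impulse smoothing; output every 0.1 h (AUC stable to well
under 0.5% against half-step refinement, asserted in the tests). Mass
balance — dose absorbed = body + cumulative eliminated — is checked at every
output point to 0.1% and a violation is a hard error, as is any
substantially negative state. The right-hand side is C code compiled with
the package; an R reference implementation of the same equations is kept in
the package and the two are cross-checked in the test suite.

## 2. Virtual population

Subject physiology is sampled log-normally per field with the central value
as the *median* (`sdlog = sqrt(log(1+CV^2))`), which preserves geometric
means and guarantees positivity. Central values are widely published human
defaults:

| field | central | CV% |
|---|---|---|
| body weight | 75 kg | 20 |
| liver weight | 1650 g | 20 |
| hepatic blood flow | 87 L/h | 15 |
| villous (enterocyte) blood flow | 18 L/h | 20 |
| microsomal protein / g liver | 40 mg/g | 30 |
| hepatic CYP3A4 | 137 pmol/mg | 40 |
| gut CYP3A4 (total) | 66.3 nmol | 40 |
| CYP2C19 / 2D6 / 2C8 / 2C9 | 14 / 8 / 24 / 73 pmol/mg | 45–60 |
| GFR scalar, binding-protein scalar | 1 | 15 / 10 |
| hematocrit | 0.45 (truncated to (0.2, 0.6)) | 8 |

The binding-protein scalar scales the concentration of the binding protein,
so \(f_u' = f_u / (s(1-f_u) + f_u)\). Requested age ranges are clipped into
the allowed window with a message (out-of-range bounds replaced by the
nearest allowed value).

The **cancer** population is derived from the healthy spec by documented
modifiers: binding-protein scalar 1.25 (raised alpha-1-acid glycoprotein,
lowering \(f_u\) of basic drugs), hepatic/gut CYP3A4 abundance × 0.75/0.85,
lower body weight and hematocrit, older demographics. The underlying
patient population file of the commercial platform is proprietary; these
modifiers are a calibrated design choice whose purpose is to reproduce the
qualitative orderings (lower victim-side DDI magnitude, higher perpetrator
exposure) rather than any specific patient physiology, and they are never
asserted as fact.

## 3. fm/fe accounting

`fm_fe_partition()` divides each pathway's eliminated mass in a window by
the total eliminated in that window, computed from the cumulative flux
states. The denominator covers *systemic* pathways only — pre-systemic
gut-wall metabolism is excluded (`scope = "all"` includes it) — because the
published fm/fe convention expresses fractions relative to systemic
clearance, and the day-1 split for a drug with any gut extraction could not
otherwise sum to 1 over the liver + renal + biliary pathways. With repeated
dosing, the first dosing interval gives the day-1 split; a late interval
gives the steady-state split, and under auto-TDI/induction the two differ —
the central mechanistic output of the model.

## 4. Retrograde ("middle-out") calibration

`retrograde_clint()` back-calculates per-enzyme intrinsic clearances (and
renal/biliary clearance when targeted) so that (a) the simulated
dose-normalized AUC\(_{inf}\) under a reference regimen matches its target
within 0.5% and (b) the day-1 fm/fe split matches per pathway within 0.2
percentage points. The solver alternates multiplicative updates — each
pathway scaled by target/achieved fraction, then all pathways scaled
together to the exposure target — iterated because renal/biliary fractions
depend on total clearance and the day-1 CYP3A4 flux is mildly nonlinear
under auto-interaction. The scheme typically converges in well under ten
iterations; step sizes are clamped (×0.2–5 per pathway, ×0.25–4 overall) for
robustness. fm is *defined* on first-dose fluxes; the steady-state split is
an output, never a calibration target. `refine_by_accumulation()` shifts the
split between CYP3A4 and the lumped additional pathway by monotone bisection
(more CYP3A4 under auto-TDI ⇒ larger accumulation ratio), re-running the
retrograde step per candidate, and is a no-op when the observed accumulation
range is already met.

The shipped fedratinib fixture was produced this way. Its calibration
targets: dose-normalized AUC\(_{inf}\)
28.5 ng·h/mL per mg (300 mg single dose), single-dose Cmax ≈ 529 ng/mL,
day-1 fm/fe 64/16/2/11/7 (%), steady-state hepatic CYP3A4 share ≈ 34%, AUC
accumulation ratio ≈ 2.5 at 400 mg QD, and the interaction magnitudes of
§6. Absorption (`ka = 0.8/h`, lag 0.25 h), distribution (`vss = 2.60 L/kg`,
`v_sac = 6 L/kg`, `q_sac = 2.53 L/h`) and the interaction constants were
fixed by that calibration; the acceptance script re-derives the intrinsic
clearances from the same targets at run time rather than trusting the
stored values.

## 5. Virtual trials and statistics

DDI studies are paired: the victim is simulated alone and co-administered in
the *same* subjects (identical sampled physiology), the design implied by
within-subject geometric-mean ratios. Geometric means are
`exp(mean(log x))`; the 90% CI of the GM ratio uses the t-distribution on
the paired log-ratios pooled across all subjects of all virtual trials (whether such CIs
should pool subjects or per-trial means is a convention choice; pooling
across subjects is this package's choice, and `n` is reported alongside). Exposure metrics follow the study type: AUC\(_{inf}\)
(linear-up/log-down trapezoid plus \(C_{last}/\lambda_z\)) for single-dose
victims, AUC\(_\tau\) at steady state for QD victims. \(\lambda_z\) is
chosen by best adjusted R² over the last 3–12 post-peak points — an explicit
rule, since vendor defaults differ. The prediction error convention is
`PE = (GM_pred − GM_obs)/GM_obs × 100%`.

Default replication is 10 virtual trials × 10 subjects (100 subjects per
arm), the scale at which all stochastic quantities in the tests and the
acceptance script are computed; it keeps the full acceptance run around a
minute on one CPU while the paired design makes GM ratios stable to a few
percent across seeds.

## 6. Compound fixtures and their provenance

Thirteen fixtures ship as editable YAML (`inst/extdata/compounds/`), each
with a provenance note per interaction constant. The perpetrator/probe
parameter values of the commercial library are not public; fixtures are
literature-informed for PK shape and *calibrated* for interaction behavior:

* **ketoconazole** (200 mg BID) — reversible CYP3A4 inhibitor, calibrated so
  the paired fedratinib 300 mg single-dose study reproduces the predicted
  AUC ratio ≈ 3.17 / Cmax ratio ≈ 2.09. With that constant its midazolam
  index effect (≈2.9×) sits *below* the regulatory strong threshold: in this
  model fedratinib's auto-TDI amplifies the victim-side ratio, so no
  ketoconazole parameterization can reproduce the target fedratinib ratio
  and a ≥5× midazolam effect simultaneously. The fedratinib interaction is
  the quantity this package is built to reproduce, so it wins;
  **itraconazole** is instead calibrated to the strong class
  (midazolam AUC ratio ≈ 5.8) and serves as the strong-inhibitor exemplar.
* **erythromycin / diltiazem** — mechanism-based inactivators calibrated to
  the moderate class (midazolam AUC ratio ≈ 2.1–2.2).
* **fluconazole** — dual CYP2C19/CYP3A4 reversible inhibitor (fedratinib
  single-dose AUC ratio ≈ 4.4).
* **efavirenz / rifampin** — moderate / strong CYP3A4 inducers (victim
  ratios ≈ 0.3 / ≈ 0.16).
* **midazolam** — sensitive CYP3A4 index substrate, hepatic fm ≈ 0.90 plus
  enterocyte extraction, tuned so the fedratinib 500 mg QD cocktail study
  gives AUC ratio ≈ 4.26 and Cmax ratio ≈ 2.0.
* **repaglinide / warfarin / omeprazole / metoprolol** — CYP2C8 / 2C9 / 2C19
  / 2D6 probes; fedratinib's reversible constants for those enzymes are
  calibrated to the corresponding predicted ratios (≈1.46 / ≈1.00 / ≈1.46 /
  ≈1.15).

Fedratinib's gut CYP3A4 entry carries reversible inhibition plus a weaker
inactivation term than the liver entry (and the same induction): a
liver-strength gut TDI would fully inactivate enterocyte CYP3A4 at steady
state, erasing the gut component that the single-dose ketoconazole Cmax
ratio requires. The split parameterization reproduces both the single-dose
and the steady-state interaction magnitudes and is recorded in the fixture.

## 7. Synthetic data generator

`generate_observed()` multiplies the engine's central-subject profile by
i.i.d. log-normal residual error (`sigma = sqrt(log(1+CV^2))`) per subject
and sample; `make_fixture_suite()` writes single-dose 300/500 mg and
repeated-dose 300/400/500 mg QD studies with rich sampling after the first
dose and after the cycle-2 day-1 dose (28-day cycles), each with a JSON
truth sidecar, byte-identical for a fixed seed. The generator emulates the
*statistical* structure the calibration assumes — a mechanistic mean
profile with multiplicative noise. It does not emulate between-subject PK
variability within a study arm, between-study heterogeneity, BLQ censoring
or dropout; passing recovery tests therefore demonstrates the estimators
are consistent under the stated error model, not that they are robust to
real clinical-data pathologies.

## 8. Known limitations

* Transporter-mediated interactions are parsed but inactive; predictions
  for transporter substrates are out of scope.
* Perpetrator effects on CYP2C19/CYP2D6 substrates are mechanically
  implemented but carry the reversible constants' calibration only; they
  should not be treated as validated predictions (the underlying in vitro
  basis under-predicts the clinical observations).
* The saturable enterocyte self-inhibition that carries the gut component
  of the ketoconazole interaction also makes steady-state exposure mildly
  (~20%) supra-proportional from 300 to 400 mg QD — at the edge of
  "approximately dose-proportional"; the fixture-suite test asserts a 30%
  band for this reason.
* Hematocrit pathology, permeability-limited absorption, enterohepatic
  recirculation and metabolite kinetics are not modeled.
* The cancer population is a calibrated construct (see §2), not a validated
  patient physiology.
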