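---
title: "Modelling hepatic cholesterol homeostasis and its ageing perturbations"
author: "cholsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling hepatic cholesterol homeostasis and its ageing perturbations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cholsim)
```

## The model

`cholsim` implements a deterministic kinetic model of intracellular
cholesterol homeostasis in the hepatocyte: 30 reactions over 22 dynamic
species, with 13 constant boundary pools acting as sources and sinks. The
network has four functional blocks:

1. **Biosynthesis (R1–R14).** Acetyl-CoA enters from a precursor pool
   (R1), interconverts with acetoacetyl-CoA (R2) and condenses with it to
   HMG-CoA (R3). HMG-CoA reductase (HMGCR) converts HMG-CoA to mevalonate
   (R4) — the pathway's rate-limiting step. Two phosphorylations and a
   decarboxylation yield isopentenyl-PP (R5–R7), which isomerises to
   dimethylallyl-PP (R8); successive prenyl condensations (R9, R10, each
   consuming a further IPP) give farnesyl-PP, and the sterol arm
   (R11–R14) lumps squalene synthesis, epoxidation, cyclisation to
   lanosterol and the post-lanosterol reactions into single steps ending
   in free cholesterol (FC).
2. **Esterification and lipoprotein turnover (R15–R21).** ACAT2
   esterifies FC to cholesteryl esters (R15); cholesteryl ester hydrolase
   reverses this (R16). CE flows into circulating LDL cholesterol
   (R17–R18 as the VLDL→LDL→clearance lump), while receptor-mediated
   reuptake (R21, catalysed by the LDL receptor pool) returns LDL-C to
   hepatic FC.
3. **Sterol-regulated receptor synthesis (R19–R20, R22–R23).** SREBP-2
   processing is inhibited by FC through a saturating term; nuclear
   SREBP-2 in turn drives LDL receptor synthesis on top of a basal rate.
   This is the classical negative feedback: cholesterol loading lowers
   receptor numbers.
4. **Redox and enzyme turnover (R24–R30).** ROS are produced at a
   constant rate and neutralised by a bimolecular reaction with the
   antioxidant pool (R26); antioxidant production (R24) carries a
   redox-responsive induction term (basal plus a gain proportional to
   ROS). HMGCR and ACAT2 protein turnover (R27–R30) is simulated, but the
   catalytic activities of R4/R15 are carried as lumped Vmax values that
   the in-silico experiments set directly.

Units are µmol/µL for concentrations, minutes for time and µMoles/min for
Vmax values; the LDL receptor pool is carried in receptor counts (its
printed values are of order 3.4–3.5×10⁴, a different unit scale from the
metabolites; no conversion between the two is attempted).

## Rate laws

Rate-law families are deliberately minimal: irreversible Michaelis–Menten
for the two enzymatic steps that the experiments manipulate through a
Vmax (R4, R15); reversible mass action for the three interconversions
(R2, R6, R8); bimolecular mass action for the condensations and ROS
neutralisation (R3, R9, R10, R26); first-order mass action for the
remaining flux, synthesis and degradation steps; and a regulated
synthesis form `v = S·(basal + Σ gain·activator)·Π Ki/(Ki+inhibitor)` for
the three regulated productions (R19 by SREBP-2, R22 inhibited by FC, R24
induced by ROS).

Two design points deserve comment:

* **R24 induction.** With strictly constant antioxidant and ROS
  production, the difference AOX−ROS changes at a constant rate and the
  subsystem either diverges or (when production rates balance exactly)
  has a structurally zero Jacobian eigenvalue. Neither admits the
  asymptotically stable steady state the analysis requires, so
  antioxidant production carries a ROS-proportional induction term — the
  standard redox-responsive (Nrf2-like) behaviour — which makes the
  subsystem a stable node while keeping every reaction of the list
  intact.
* **R19 basal synthesis.** Receptor synthesis is basal plus
  SREBP-2-proportional rather than purely proportional, so the synthesis
  rate is positive even at zero regulator concentration, as a synthesis
  step should be.
* **ROS→HMGCR coupling.** The hypothesis that ROS activate HMGCR is
  exercised by scanning Vmax(R4) directly (a Vmax proxy); an optional
  multiplicative ROS modifier on R4 exists (`ros_gain_r4`) but ships at
  zero so the scan results are produced purely by the Vmax sweep.

## Parameters, provenance and calibration

Three constants are fixed by the source parameterization: Vmax(R4) =
1.43 µMoles/min, Vmax(R15) = 0.04 µMoles/min and the acetyl-CoA synthesis
constant k1 = 0.1. Every other constant is tagged `calibrated` in the
shipped YAML: it was fitted, by weighted least squares on relative
residuals (`calibrateModel()`, Levenberg–Marquardt on log-transformed
constants), against the packaged anchor set — the 5×5 combined
HMGCR×ACAT2 modulation grid of FC, CE, LDL-C and LDLr readouts at
3000 min plus the baseline (32.13 µmol/µL) and doubled-synthesis
(57.52 µmol/µL) acetyl-CoA readouts. Anchors are weighted 1/target², so
the ~10⁻¹-scale CE/LDL-C cells and the ~10¹-scale FC cells contribute
comparably; the LDLr cells are down-weighted (weight 0.25) because of
their distinct unit scale. Several structural constants are
well-determined by the anchors in closed form before any fitting: the
Michaelis constant of R15 (≈4 µmol/µL) and the total CE turnover rate
(k16+k17 ≈ 0.1/min) follow directly from ratios of grid cells, and the
acetyl-CoA subsystem constants from the two acetyl-CoA anchors.

The calibration target is deliberately the *transient* state: all
experiment readouts are taken at t = 3000 min from the baseline initial
state, not at the asymptotic steady state — at 3000 min the cholesterol
pools are still filling, which is exactly why lowering ACAT2 activity
shows such large FC excursions. The steady state proper (used by the
control analysis) lies close to the 3000-min baseline state and is
asymptotically stable.

`makeFixture()` exposes three parameterizations: `baseline` (the shipped
model), `tiny_chain` (a three-species linear chain whose steady state has
the closed form k_in/k, used as an analytic oracle throughout the tests)
and `perturbed` (baseline with a seeded ±10% multiplicative jitter for
robustness tests).

What the anchors do *not* constrain: absolute concentrations of the
intermediate isoprenoids (MV through lanosterol), the redox subsystem and
the enzyme-turnover pools. Their constants are set to round, plausible
values (turnover times of minutes to hours) and tagged `calibrated` like
all fitted values; conclusions about those pools should not be read off
this model. Passing the anchor tests demonstrates that the model
reproduces the printed experiment readouts, not that the underlying
constants equal the (unpublished) originals — parameter identifiability
from 102 aggregate readouts is necessarily partial.

## Numerical choices

* **Integration**: stiff solver (`deSolve::lsoda`) with the analytic
  Jacobian assembled from closed-form rate-law derivatives; rtol 1e-8,
  atol 1e-10. The network mixes fast isomerisations (minutes) with slow
  receptor turnover (hours), hence the stiff method.
* **Non-negativity**: rate laws vanish at zero substrate, so exact
  solutions stay non-negative. Clipping is forbidden; any numerical
  excursion below −1e-12 aborts with a diagnostic naming the species.
* **Steady state**: damped Newton on the right-hand side with analytic
  Jacobian, long-time integration as fallback when Newton stalls;
  residual tolerance max|ds/dt| < 1e-6 (configurable). Stability is
  decided by the eigenvalue real parts of the Jacobian over dynamic
  species.
* **MCA**: "perturbing step i" means scaling its whole rate expression by
  1±δ (activity scaling, δ = 1e-3 by default), re-solving the steady
  state and forming central log-ratios. The perturbed re-solves converge
  on the relative Newton step (1e-11) rather than an absolute residual,
  because perturbations of low-flux steps (e.g. receptor-mediated
  reuptake) move the residual by less than any sensible absolute
  tolerance. The elasticity-based matrix method — with link-matrix
  reduction should the stoichiometry ever be rank-deficient; the shipped
  network has full rank 22 — provides the independent cross-check, and
  both routes satisfy the summation theorems to well below 1e-3.
* **Elasticities** at zero flux or zero concentration are reported as
  NA with an `undefined` flag, never silently zero.
* **Calibration**: the Levenberg–Marquardt finite-difference Jacobian
  uses a step (epsfcn 1e-8, i.e. ~1e-4 relative) chosen to sit well above
  integration noise; with the library default the derivative estimates
  are noise and the fit stalls at its starting point.

Problem sizes are modest throughout — the 5×5 scan is 25 integrations of
a 22-species system to 3000 min, the control analysis 60 Newton
re-solves — so the full analysis suite runs in seconds to a few minutes.

## Known limitations

* The model is a single-compartment hepatocyte: no plasma compartment
  kinetics, no VLDL/IDL intermediates (R17–R18 lump them), no PCSK9
  branch, no intestinal absorption.
* Appendix-level constants of the source parameterization were not
  published; all non-printed constants are calibrated against readouts,
  so individual constants are effective, not measured, quantities.
* The LDLr unit question is unresolved upstream; the receptor pool is
  carried in its own count-like unit and only compared against readouts
  in that unit.
* The ageing scenario is a parameter composite (doubled Vmax(R4), halved
  Vmax(R15)) applied instantaneously, not a dynamic ageing trajectory.
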