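---
title: "Methods: a reduced population-PBPK model for end-stage renal disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a reduced population-PBPK model for end-stage renal disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esrdpbpk)
```

## The problem

End-stage renal disease (ESRD, GFR < 15 mL/min/1.73 m²) changes drug
exposure far beyond the loss of renal filtration: uremia alters the
abundance of drug-metabolising enzymes and transporters (DMETs) in the gut,
liver and kidney, plasma protein levels shift the unbound fraction, and
gastrointestinal transit slows. The consequence is that both renally and
non-renally cleared drugs behave differently, drug–drug interactions are
modulated by the disease (drug–drug–disease interactions), and
inter-individual variability is large.

`esrdpbpk` implements an analysis chain for this problem:

1. **Virtual populations** — sample Chinese healthy-volunteer (HV) and
   ESRD individuals from demographic polynomials, creatinine strata,
   blood-chemistry distributions, kidney-size parameters and GI residence
   times; compute eGFR (CKD-EPI 2009) and the eGFR-scaled fraction of
   renal OAT3 secretory function.
2. **A reduced mechanistic PBPK simulator** expressing the pathways the
   analysis manipulates: gut CYP3A4 / P-gp / BCRP, hepatic OATP1B1/3 and
   CYP3A4, renal filtration + OAT3/BCRP secretion, a perfusion-limited
   muscle compartment, competitive and mechanism-based inhibition, and a
   lumped prodrug conversion.
3. **Back-calculation** — invert the simulated ESRD/HV exposure ratio
   (AUCR) against an observed AUCR to estimate one abundance multiplier at
   a time, over a sequential five-probe protocol (CYP3A4 → intestinal
   P-gp → OATP1B1/3 → ileal BCRP → multi-pathway validation).
4. **Risk scenarios** — muscle exposure of statins and DDI magnitudes in
   HV vs ESRD, plus Morris elementary-effects screening of the
   physiological inputs.
5. **Individual correction** — non-compartmental CL/F from
   concentration–time tables, a correlation screen of microbiome/lab
   covariates against the PBPK/reference clearance ratio, LASSO selection
   at the cross-validation-minimising penalty, OLS refit, and a division
   correction of the individual PBPK clearance.

Everything runs on synthetic data generated inside the package.

## Population model

Typical body height is a sex-specific quadratic in age and weight a
log-linear function of height. Any parameter reported as "(mean, CV%)" is
sampled **lognormally parameterised to match that mean and CV** — this
guarantees positivity and is the convention of platform PBPK simulators.
Serum creatinine is sampled within sex × age strata; the printed female
bands overlap, so they are normalised to disjoint bands [18, 30), [30, 60),
[60, ∞) under a most-specific-band-wins reading (males: [18, 50),
[50, ∞)). eGFR uses the 2009 creatinine CKD-EPI equation without the race
coefficient (Chinese population; 88.4 µmol/L per mg/dL).

Renal OAT3 secretory function scales with kidney function as
$f_{OAT} = 1 - e^{-(eGFR/43.9)^{0.9}}$, a saturating, strictly increasing
function that is ≈ 0.247 at the ESRD population mean eGFR of
10.81 mL/min/1.73 m² and → 1 in health. The shipped ESRD profile stores
the conventional three-decimal value 0.246. HV individuals have
$f_{OAT} = 1$ by construction.

Choices the inputs left open, decided once here:

* **Demographic inter-individual variability**: the source tables print
  only typical-value equations, so lognormal IIV of CV 3% (height) and
  15% (weight) is added — documented placeholders of anthropometric
  magnitude.
* **Kidney volume**: the functional form behind the printed coefficients
  is not published; we use
  `volume = baseline + bw_coeff·BW + bh_coeff·(BH/100)` with lognormal
  CV 23.4%. Kidney size only scales active secretion through a
  mean-one individual factor (sampled volume over its deterministic
  value), so this placeholder does not shift population contrasts.
* **Phenotype frequencies** default to all-extensive (activity-score row
  1); they are config-overridable, since population frequencies are not
  part of the model configuration.
* **The HV comparator spec** mirrors a platform Chinese-HV population;
  values not printed anywhere (HV creatinine, GI residence, kidney
  coefficients) are placeholders chosen so the ESRD values are
  prolongations (gastric residence ×2, colon drug mean residence time
  ×1.5).

## The reduced PBPK structure

The paper-scale analysis runs on a proprietary full-PBPK platform; this
package instead defines a **reduced, fully documented ODE system** that
expresses the same pathway dependencies. Absolute clinical exposures are
not the target — pathway-ratio behaviour is.

States (amounts, mg): stomach → jejunum → ileum → colon lumen (first-order
transit; rates from the individual's gastric residence and colonic mean
residence time), one enterocyte pool per segment (absorption `ka`,
basolateral exit 15 h⁻¹, apical efflux returning drug to the lumen — P-gp
in the jejunum, BCRP in the ileum — and gut CYP3A4 loss), an optional
permeability-limited liver (extracellular ↔ intracellular: passive PS +
OATP1B1/3 uptake on the unbound extracellular side, CYP3A4 metabolism and
biliary efflux from the intracellular side), a central plasma compartment,
a perfusion-limited muscle compartment (partition coefficient
`kp_muscle`), renal elimination as unbound filtration (fu × eGFR, scaled
from a 120 mL/min/1.73 m² reference) plus OAT3/BCRP secretion, and
per-pathway cumulative elimination states for mass-balance auditing.
Prodrugs (the dabigatran archetype) run the gut states as prodrug and
convert first-order into the systemically disposed active moiety; the
plasma readout is the active moiety and the two-step esterase cascade is
deliberately lumped.

Individualisation: the unbound fraction scales with the subject's binding
protein (HSA or AGP) around the population mean via a single-site binding
relation, with the population-typical fu in ESRD given by the measured
ESRD/HV fu ratio of each drug (dabigatran's binding is unchanged);
hepatic and muscle plasma flows scale with (1 − hematocrit) and
allometric body weight; the liver compartment is instantiated only for
drugs with hepatic disposition parameters, so degenerate one- and
two-compartment configurations reduce exactly to their closed forms.

Inhibition is competitive, `1/(1 + I_u/K_i)` at a static unbound
perpetrator exposure; mechanism-based inactivation (the clarithromycin
archetype) attenuates the enzyme amount to its turnover steady state,
`k_deg / (k_deg + k_inact·I_u/(K_I + I_u))` with `k_deg = 0.03 h⁻¹`.
OATP1B1 and OATP1B3 are locked to move with identical folds.

Numerics: LSODA with relative tolerance 1e-8, absolute 1e-10, output grid
0.05 h; the right-hand side is compiled C, with a line-for-line R
reference implementation cross-checked in the test suite. Doses at t = 0
enter the initial condition; later doses are solver events. Mass balance
is asserted to 1e-6 of dose (observed ~1e-14).

Intrinsic clearances are scaled to whole-organ clearances through fixed,
documented constants (`pbpkScales()`): microsomal protein 40 mg/g ×
1560 g liver for enzymes, single lumped scalars per tissue for
transporters. Where the source prints an anchor it is used directly
(ileal BCRP CLint,T 6 µL/min for the atorvastatin archetype; renal OAT3
CLint,T 150 µL/min/10⁶ cells for rosuvastatin, with the renal scalar set
so the renal route carries ≈ 28% of rosuvastatin clearance in HV); all
other fixture values are placeholders of plausible magnitude, documented
in `drugFixture()`.

## Back-calculation

`predictAUCR()` simulates **matched** virtual cohorts: the HV and ESRD
samplers consume identical random-number streams (one fixed draw layout
per individual), so demographic deviates are shared and the exposure
ratio is a deterministic function of the abundance multipliers given the
seed. `backcalcAbundance()` then bisects on the log multiplier over
[0.01, 10]. The HV arm does not depend on the free multiplier and is
simulated once.

Convergence: the iteration stops when |pred/obs − 1| ≤ `tol` or the
bracket is narrower than `mtol = 1e-4` on the multiplier scale. `tol`
defaults to 1e-5 — deliberately sharp, because weakly identified pathways
(jejunal P-gp, ileal BCRP) move the exposure ratio slowly, and a loose
exposure match would leave a 1–2% multiplier error; with the sharp
default the bracket criterion governs and the estimate converges to the
multiplier itself. A step is *accepted* when the achieved pred/obs ratio
falls within the inclusive 0.8–1.25 window ("falling within" is read as
inclusive); 0.5–2 is used for the wider drug-model validation checks.

The sequential protocol estimates hepatic CYP3A4 (midazolam), jejunal
P-gp (dabigatran), the locked OATP1B pair (pitavastatin), then ileal BCRP
(rosuvastatin) with OATP1B frozen at its estimate and OAT3 at the
eGFR-scaled 0.246; atorvastatin closes the loop as a validation-only
prediction. Order matters and the tests document it: without the OATP1B
reduction fixed first, the rosuvastatin observation is not attainable by
ileal BCRP alone. Observed AUCRs can be supplied as scalars or computed
from two concentration-table sets via the NCA module; the synthetic
generator is the test surface, since the clinical tables are not
published.

## NCA

AUC uses the linear-up/log-down rule: the logarithmic trapezoid on
declining intervals with positive endpoints, the linear trapezoid on
rising/flat intervals or when an endpoint is zero (the log form is
undefined there). The terminal slope maximises adjusted R² over suffixes
of the post-Cmax points (Cmax excluded, minimum 3 points); AUC(0–∞) adds
Clast/λz, and CL/F = dose / AUC(0–∞), falling back (flagged) to AUC(0–t)
when no terminal phase exists. The analysis window is 0–72 h to match the
simulation span of the clearance-ratio stage.

## Scenarios and sensitivity

DDI scenarios simulate the victim with and without the perpetrator on
identical cohorts and report geometric-mean AUC and Cmax ratios
(`AUCR_w/w-o`). Muscle exposure compares ESRD vs HV muscle AUC under a
single dose (0–72 h) or the last interval of a repeated regimen; because
single-dose windows truncate the longer ESRD terminal phase, the
multiple-dose ratio is the larger one — the direction the risk argument
needs. The trial design defaults to 10 trials × 10 subjects, 50% female,
ages 20–70.

Morris screening uses the classic trajectory design (4 levels,
Δ = 2/3, default r = 20 trajectories; the PBPK wrapper uses smaller r in
tests) and reports μ* and σ on unit-scaled inputs, so an additive-linear
model's μ* equals |coefficient × range|. The screened physiological set
includes the cardiac-output scalar and liver density, which the reduced
model does not use: their μ* is structurally zero, and the tests pin that
divergence down rather than hide it.

## Individual-factor selection

The per-subject ratio CL/F(PBPK)/CL/F(reference) is screened against
candidate covariates by Spearman correlation (robust at n ≈ 10; Pearson
selectable — the method choice was left open by the source and Spearman
is the safer small-sample default), retaining p < 0.05. Retained
covariates enter a LASSO (internally standardised); the penalty is chosen
at the cross-validated minimum (leave-one-out for n ≤ 12, else 10-fold),
and the surviving covariates are refit by ordinary least squares on their
raw scales. The refit reflects a reading of the published equations as
unshrunken coefficients in raw units (relative abundance, U/L, µmol/L);
the shipped `dabCorrectionEquation()` and `rsvCorrectionEquation()`
encode the published dabigatran and rosuvastatin equations. The ratio
convention: ratio > 1 means the PBPK model over-predicts clearance, so
the correction divides. Degenerate inputs collapse gracefully: constant
response or rank-0 design gives an intercept-only equation; a single
screened covariate is padded with an inert zero column (the LASSO
implementation requires two); perfectly collinear duplicates resolve to
one refit term in column order.

## The synthetic generator: what it does and does not emulate

`genCohortCovariates()` draws genus relative abundances marginally
lognormal, with the two planted genera sharing a latent community factor
(gut genera co-vary; this also gives each planted covariate a detectable
marginal correlation), and labs lognormal; the true clearance ratio is a
planted linear model plus normal noise (default CV 2% of the mean ratio).
`genObservedPK()` simulates each subject and applies mean-one lognormal
proportional error (default 20%, typical of microdose bioanalysis) at a
standard 15-point schedule including the predose sample. Abundances are
*marginally* lognormal, not compositional — the analysis consumes
per-genus columns, not simplex compositions — and no sequencing-level
noise is emulated. Passing the recovery tests therefore shows the
selection machinery works when its assumptions hold; it does not certify
performance on real 16S data.

The recovery property test uses two planted plus two nuisance candidates.
That count is implied by its own target: each null covariate passes a
p < 0.05 screen ~4.8% of the time, so an exact-set recovery rate of ≥ 90%
is only reachable with ≤ 2 nuisance candidates (0.952² ≈ 0.906) — the
four-covariate scale of the published rosuvastatin equation.

## Problem sizes

Calibration and scenario defaults in the tests and the acceptance script
use 2 trials × 10 matched subjects per arm: with common random numbers
the self-consistency recovery is independent of cohort size, so the small
matched design is the appropriate one. Full population summaries default
to the 10 × 10 trial design. The Monte-Carlo checks use 4000 sampled
individuals (creatinine strata) and 100 seeded replicates (covariate
recovery).

## Known limitations

* Absolute exposures depend on placeholder drug parameters and lumped
  organ scalars; only the configuration anchors and ratio/directional
  behaviour are validated.
* No saturable transport or metabolism: microdose-linear by construction;
  known nonlinearity of intestinal P-gp at therapeutic doses is out of
  scope.
* No enterohepatic recirculation, dissolution/precipitation, metabolite
  cascades beyond one conversion, or hemodialysis kinetics.
* The DDI perpetrators use static unbound exposures with placeholder
  interaction constants; scenario conclusions are directional.
* One- and two-compartment closed-form agreement is exact only for the
  degenerate configurations that disable the liver; drugs with hepatic
  disposition always carry the liver sub-model.
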