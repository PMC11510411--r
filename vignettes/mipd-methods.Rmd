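---
title: "Model-informed precision dosing of ustekinumab: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-informed precision dosing of ustekinumab: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(utkmipd)
```

## The problem

Ustekinumab (UTK) is dosed in plaque psoriasis from a label that fixes dose
(45 or 90 mg by body weight) and interval (q12w after induction). Real-world
response is heterogeneous: some patients stay clear on less drug, others
relapse before the next injection. `utkmipd` implements a model-informed
precision dosing (MIPD) workflow that turns sparse therapeutic drug
monitoring (TDM) concentrations and routine PASI scores into a per-patient
probability statement about candidate regimens, and selects the least
intensive regimen that keeps the probability of an absolute PASI of at most
1 above 90%.

## Structural models

**PK.** A linear two-compartment model with first-order subcutaneous
absorption. Because only subcutaneous data are involved, bioavailability is
not separately identifiable and the parameterization is apparent (CL/F, Q/F,
V2/F, V3/F with F = 1). The central concentration after each dose is the
closed-form tri-exponential solution; multiple doses superpose. The
disposition parameters scale allometrically with body weight — the only
covariate retained — as `P_i = P_typ (WT/70)^e` with `e = 0.75` for the
clearances and `1` for the volumes. The shipped typical values
(ka 0.35/day, CL/F 0.465 L/day, V2/F 4.6 L, Q/F 0.4 L/day, V3/F 2.8 L) are
**illustrative defaults for testing and simulation**; the integrated
published UTK model should be substituted for real use, and the exponents,
reference weight and every typical value are plain configuration fields.

**PD.** PASI follows indirect-response turnover: lesions form at a zero-order
rate `kin` and remit at a first-order rate `kout`; drug inhibits formation
through a saturable Imax function,

$$\frac{d\,\mathrm{PASI}}{dt} = k_{in}\left(1 - \frac{I_{max} C(t)}{IC_{50} + C(t)}\right) - k_{out}\,\mathrm{PASI},$$

with the system at steady state at baseline, so `kin = kout * PASI0`
identically. Defaults are the final population estimates:
`kout` 0.016/day, `Imax` 0.97, `IC50` 0.07 mg/L (a fixed literature
constant, never estimated), IIV on `kout` of 0.5587 (log-scale SD), PD
residual log-SD 0.86.

**Residual errors and the baseline.** The PD residual is multiplicative
log-normal; the printed residual magnitude (0.86) is interpreted as the
log-scale SD, which makes it coherent with the B2 baseline method: the
observed baseline `PASI_i0` measures the true individual baseline through
`PASI_i = PASI_i0 * exp(eta_RV)` with `Var(eta_RV)` constrained equal to the
residual variance during estimation. A proportional-on-natural-scale PD
error would be a one-line change but is deliberately not the default, to
keep the baseline model and the observation model on the same scale. PK
residuals are log-normal ("exponential-proportional"), SD 0.2 by default:
with this form the empirical-Bayes mode of a subject whose datum sits
exactly on the typical prediction is exactly zero, which a
proportional-normal error does not give (its `log f(eta)` normalization
shifts the mode).

## Estimation

Estimation is sequential, mirroring clinical use: individual PK parameters
are fixed at their empirical-Bayes (MAP) modes given the population PK
prior (IIV log-SD 0.3 on CL and V2, an illustrative value since no PK IIV is
printed for this cohort), then the population PD parameters
(`kout`, `Imax`, `omega_kout`, `sigma_pd`) are estimated by maximizing the
marginal likelihood with `IC50` fixed. Per subject two random effects are
marginalized: the B2 baseline deviation `eta_RV` integrates out *exactly* —
it enters the log-scale observation model linearly with prior variance tied
to the residual variance, so `log y | eta_kout` is multivariate normal with
covariance `sigma^2 (I + 11')` — and `eta_kout` is handled by
deterministic one-dimensional quadrature (trapezoid nodes placed finely
around the located conditional mode and coarsely over the prior scale). A
pure Laplace expansion is avoided: the conditional profile in `eta_kout`
develops fold points where its curvature vanishes, at which the Laplace
log-determinant term diverges and attracts the outer optimizer into
spurious spikes. Concentrations below the assay limit of quantification
(0.63 mg/L) are excluded from the PK likelihood and counted (a censored
likelihood is a config option left off by default because the source
analysis states no BLQ rule); PASI values below 0.1 are floored at 0.1
before the log transform (PASI 0 occurs in practice and the log-normal
density is undefined there), with every application logged.

Numerical choices that matter:

- The PD ODE is linear in PASI given `C(t)`, so the production solver is an
  exact exponential recursion with trapezoidal quadrature of the inhibition
  input on a uniform grid (default step 0.5 days in estimation and regimen
  simulation, 0.25 in the cohort generator). The drug-free case is
  reproduced exactly; against an
  adaptive-step integrator the solution agrees to ~1e-3 relative at
  h = 0.1. An adaptive deSolve route (`method = "ode"`, rtol 1e-8) is kept
  as an independent cross-check and oracle.
- Every marginal-likelihood evaluation locates the conditional mode from a
  fixed 7-point start scan plus polish and then integrates on nodes derived
  only from the current parameters, making the outer surface deterministic
  (no warm-start history, which corrupts finite-difference gradients); the
  coarse prior-scale nodes keep secondary modes in the integral even when
  the polish lands on the other one.
- The outer optimizer is bounded quasi-Newton (`nlminb`) on transformed
  parameters (logs; logit for `Imax`) from 5 starts (the first at the
  user's initial values, the rest jittered under a fixed seed), followed by
  a Nelder–Mead polish of the distinct optima: the marginal surface has
  derivative kinks where an inner mode switches basins and the simplex
  search is robust to them. The reported objective (-2 log marginal
  likelihood) is re-evaluated at the optimum by the same deterministic
  routine that `objective_value()` uses, so the two agree exactly.
- RSEs come from the observed information (finite-difference Hessian on the
  transformed scale, delta method back), the standard first-order
  approximation.

`pcvpc()` provides the simulation diagnostic: observations and simulated
replicates are rescaled by the ratio of the bin-median population
prediction to the record's own population prediction before percentiles are
compared; empty time bins are merged leftward and logged.

## Conditional distributions and clones

Dose individualization uses each patient's full conditional distribution
`p(psi_i | y_i) ∝ p(y_i | psi_i) p(psi_i)`, sampled by random-walk
Metropolis–Hastings on the log-scale deviations, initialized at the
empirical-Bayes mode. By default the sampled dimensions are `eta_kout` (the
model's only declared PD random effect) and `eta_RV` (the baseline is itself
uncertain under B2); a flag adds PK deviations for full joint uncertainty.
Defaults: burn-in 500, thinning 10, 100 retained clones, proposal SD
0.5 x prior SD adapted toward 30% acceptance during burn-in only (frozen
afterwards so retained draws come from a fixed kernel, capped at x10 / /10
of the initial scale), and a subject-derived seed so cohorts are
reproducible patient by patient. The source analysis does not state burn-in,
thinning or proposal design; thinned single-chain draws are assumed.

## Regimen simulation, selection, cost

Each clone is simulated deterministically (no residual noise on the latent
PASI) through 5 maintenance cycles of the patient's current regimen and 5
cycles of a candidate from the 45/90 mg x q8w/q12w/q16w/q20w grid, with the
PD state continuous across the switch and cycle length equal to the
interval of the regimen being given. Evaluation is at the trough instant at
the end of cycles 5 and 10 — the stated evaluation point is "at the cycle"
without a clock time, and the trough is the conservative reading. Decisions
use the latent PASI because they should reflect parameter uncertainty, not
assay noise (both points are genuinely open in the source description; the
alternatives are config switches away). The probability of target is exact
clone counting (`100 * n / N`, ties at the target count as success);
candidates at or above 90% qualify; the qualifier with minimal dose
intensity (mg/week) wins, ties going to the longer interval (fewer
injections). Classification against the current regimen: same regimen
maintains, lower intensity optimizes, higher intensifies; at equal intensity
but different shape, the longer interval counts as optimization. Induction
(weeks 0 and 4) enters only the first-year cost arithmetic
(EUR 2915.4/dose); maintenance years count `floor(52/interval)` doses, so
q12w to q16w is 4 to 3 doses, a 25% saving.

Within the grid, dominance in the *partial* order is exact on shared
clones — more drug at the same interval can only raise concentrations
everywhere and hence lower PASI. Across *different* intervals at equal dose
the comparison also behaves monotonically in practice, but the cycle-10
evaluation times differ between candidates (5 cycles of q20w last 2.5 times
longer than 5 of q8w), so monotonicity in the scalar "dose intensity" across
interval changes is not a theorem; the exposure–response summary therefore
reports regimens sorted by intensity without asserting a total order.

## The synthetic cohort

`generate_cohort()` emulates the observed study structure: truncated-normal
body weight (92 ± 18.4 kg on [70, 135]) and observed baseline PASI
(14.4 ± 6.23 on [5, 31.9]) — the simplest distributions matching all four
printed summaries, sampled by rejection; current regimens drawn from the
empirical frequency table (e.g. 8/23 on 90 mg q12w); PK samples from the
scheduled TDM template (pre-dose trough plus weeks 2–18 after a maintenance
dose, anchored mid follow-up), thinned to 2–5 per patient with mean ~3.3 so
a 23-patient cohort lands near the observed 75 concentrations; PASI visits
every 3 months in year one then every 6 months (~117 observations plus
baselines); assay censoring flags outside 0.63–20 mg/L. Hidden truths (true
parameters and latent trajectories) ride along for recovery scoring.

What it does **not** emulate: dropout, non-adherence, time-varying weight,
comorbidity effects, anti-drug antibodies, or any real-data misspecification
of the structural model — passing recovery tests on these cohorts shows the
estimator is consistent under the model, not that the model is right for
any particular clinic's data.

## Problem sizes and reproducibility

The bundled analyses use the cohort sizes the estimator is meant for: the
recovery experiment simulates 100 virtual patients with biweekly PASI
sampling over 18 months (the acceptance script re-runs exactly this), and
the worked MIPD analysis under `analysis/` uses a 23-patient cohort with 100
clones per patient. All randomness flows from explicit seeds (master seed
plus `derive_seed()` offsets), reruns are byte-identical, and every pipeline
output embeds its seed and a hash of the analysis configuration.

## Known limitations

- PK typical values are placeholders; conclusions about absolute
  concentrations (e.g. trough targets) depend on substituting a published
  UTK model.
- The inner quadrature and the PD grid solver leave ~1e-3 relative error on
  the objective; profile-likelihood or SAEM refits would be the next step if
  estimates sat near a tolerance boundary.
- The conditional sampler defaults to PD-only uncertainty; enabling PK
  dimensions widens the clone spread and can flip borderline decisions.
- Nonlinear (target-mediated) elimination, immunogenicity and non-SC routes
  are out of scope.
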