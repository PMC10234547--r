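---
title: "Methods: population pharmacokinetics of single-dose oral ivermectin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population pharmacokinetics of single-dose oral ivermectin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Ivermectin (IVM) is dosed at 200 µg/kg in mass drug administration against
lymphatic filariasis, and its exposure after a single oral dose is highly
variable between subjects. `ivmpoppk` implements the full population-PK
workflow for this setting — structural model, nonlinear mixed-effects
estimation, covariate selection, validation diagnostics, and dose-exposure
simulation — together with a synthetic-cohort generator so that every stage
is exercised end to end without access to clinical data. This vignette is
the package's own account of the model, the numerical choices, and what the
synthetic experiments do and do not demonstrate.

## Structural model

Drug enters a depot compartment as a **zero-order infusion** of duration
`Tk0` (h) starting `Tlag` (h) after the dose, while the depot simultaneously
drains into the central compartment at the **first-order rate** `Ka` (1/h).
Disposition is a standard two-compartment linear model: elimination `CL/Vc`
from the central compartment and exchange `Q/Vc`, `Q/Vp` with the peripheral
compartment. All clearances and volumes are apparent (bioavailability-scaled):
`CL/F`, `Q/F` (L/h), `Vc/F`, `Vp/F` (L). Units are chosen so no conversion
factors appear anywhere: doses in µg, volumes in L, so amount/volume is
ng/mL directly.

Two readings of the depot input are possible: the infusion could fill the
depot *while* `Ka` drains it (simultaneous), or absorption could begin only
after the infusion ends (sequential). We implement the **simultaneous**
variant — the natural reading of a depot that both receives the zero-order
input and feeds the central compartment — and isolate it in a single
function (`central_amount_one_dose()`), so the alternative is a one-function
change.

The production solver is **exact**: the system seen from the depot is linear
with three real eigenvalues (the classical hybrid constants α, β, plus
`Ka`), and the zero-order window is convolved analytically, giving a
three-exponential closed form with no step-size or tolerance coupling to the
estimation layer. Two independent implementations guard it: a piecewise
matrix-exponential path over the augmented (depot, central, peripheral,
eliminated) system used by `compartment_amounts()`, and a stiff ODE
integration (deSolve) in the test suite. Mass balance is asserted to 1e-8,
cross-path agreement to 1e-8, and the identity AUC₀–∞ = Dose/CL to 1e-6.
Coincident eigenvalues (e.g. `Ka` equal to α) are a measure-zero degeneracy
handled by a one-part-in-1e8 nudge.

## Population model

Individual parameters are log-normal around covariate-adjusted typical
values:

* continuous covariates enter as `(cov / cov_ref)^coefficient`;
* 0/1 covariates (sex, infection status) enter as `exp(coefficient × cat)`;
* body weight enters through **fixed allometric exponents**: 0.75 on `CL`
  and `Q`, 1 on `Vc` and `Vp`, relative to a reference weight.

The source analysis standardised weight to the study-average body weight
without printing the value; we default the reference to **64 kg**, the mean
of the emulated weight distribution (below), and make it an explicit,
overridable argument of `published_model()` — exposure under per-kg dosing
is mildly sensitive to it, fixed-dose exposure is not.

Residual error is combined additive + proportional,
`var(y|f) = σ_add² + (σ_prop f)²`. IIV is log-normal on all seven
parameters, including `Tlag` and `Tk0`; the IIV covariance can be declared
`diagonal` or `full` (estimated through a log-Cholesky factorisation that
keeps it positive semi-definite during optimisation).

The IIV magnitude is conventionally reported as CV% of the log-normal
distribution, `100·sqrt(exp(ω²) − 1)`. This convention reproduces all seven
published CV% values from their ω² estimates to the printed decimal, which
is why it was adopted over the (typographically ambiguous) printed formula.

## FOCE-I estimation

The inner problem finds each subject's empirical Bayes estimate (EBE) by
minimising

```
g(η) = Σ_j [ (y_j − f_j(η))² / v_j(η) + log v_j(η) ] + ηᵀ Ω⁻¹ η
```

with the residual variance evaluated at the candidate η (the
**interaction**). The population objective linearises `f` about the
conditional mode η̂: with `G = ∂f/∂η|η̂` (central differences, step 1e-4 on
the η scale), `C = G Ω Gᵀ + diag(v(η̂))` and
`r = y − f(η̂) + G η̂`, each subject contributes `log|C| + rᵀC⁻¹r`. The
`n·log 2π` constant is omitted, the common pharmacometric convention, so
absolute OFVs differ from software that keeps it while ΔOFV values are
unaffected.

Numerical choices, all overridable:

* inner optimiser: quasi-Newton (`nlminb`) from η = 0 with deterministic
  perturbed restarts on failure, relative tolerance 1e-10;
* outer optimiser: L-BFGS-B on transformed parameters (log typical values,
  log error SDs, log-Cholesky Ω factor, raw covariate coefficients),
  forward-difference gradients with step 1e-4, warm-started EBEs cached
  across objective calls;
* `C` Cholesky failures retry with escalating jitter and then raise a hard
  error naming the subject;
* Ω components with zero variance are pinned (pseudo-inverse on the support),
  so reduced models need no special casing;
* estimate CV% (when requested) from the inverse finite-difference Hessian
  of OFV/2 by the delta method; a non-positive-definite Hessian reports
  missing CV% rather than failing the fit.

The approximation is verified against two oracles: a linear Gaussian toy
where FOCE-I is exact (objective `log 2 + ½` for the unit-variance
one-observation model) and adaptive Gauss–Hermite quadrature
(`marginal_likelihood_quadrature()`, Golub–Welsch nodes, mode-centred and
curvature-scaled) on nonlinear toys with one or two random effects, with
agreement required within 0.5 per subject.

CWRES shares the linearisation code path with the objective — the whitening
solve produced for the OFV *is* the CWRES vector — so diagnostics can never
drift out of sync with estimation.

## Covariate selection

Stepwise forward addition (ΔOFV > 6.635, χ²₁ at p = 0.01) then backward
elimination (ΔOFV > 10.828 at p = 0.001), one coefficient per candidate per
round, ties broken by the larger drop then declaration order. Creatinine
clearance is excluded from the default candidate set because the drug is
eliminated in faeces with negligible renal excretion; weight is handled by
the fixed allometric scaling rather than as an estimated candidate. Any
step's fit can be restricted (e.g. typical values and variances held fixed)
through the same `estimate` control used everywhere; the test suite uses
such single-coefficient scans to keep selection experiments fast while
exercising the full selection engine.

## Validation machinery

**VPC** simulates replicates at the observed design and compares observed
5th/50th/95th percentiles with the 2.5–97.5% band of the same percentiles
across replicates. Bins are the nominal schedule times, because the emulated
design has a fixed common schedule; sparse bins merge into their nearest
neighbour and the merge is recorded. Simulated values below the LLOQ are
retained by default (the modelled dataset contains no below-LLOQ values);
`lloq_censor` switches censoring on for external reuse.

**Bootstrap** resamples subjects with replacement to the original size and
refits, warm-starting from the supplied estimates with one fall-back restart;
non-converged replicates are excluded, counted, and more than 20% failures
flags the result unstable.

## Synthetic cohorts: what they emulate

`study_cohort_spec()` encodes the modelled trial: 56 subjects, 57% male,
57% LF-infected, ages 18–66, weights from a truncated normal (mean 64 kg,
SD 11 kg, bounds 51–135 kg, chosen to match the published median 61.6 kg
and range 51–135 kg), liver/renal laboratory covariates drawn uniformly over
the published ranges (they are deliberately effect-free nuisance candidates
for selection experiments), 200 µg/kg dosing, samples pre-dose and at 1, 2,
3, 4, 6, 8, 12, 24, 36, 48, 72 and 168 h, LLOQ 0.1 ng/mL, and the 168-h
sample dropped for 4 subjects. That yields 56×13 − 4 = 724 sample records,
matching the published accounting; the pre-dose records carry zero
concentration in treatment-naïve subjects and are flagged `MDV = 1`, so the
fit-eligible count is 56×12 − 4 minus any below-LLOQ flags. The exact
pre-dose/post-dose decomposition of the published 724 is not stated in the
source; this is one consistent reading, and both counts are exposed
(`total_samples()`, `n_observations()`).

Observed values are `f·(1 + ε_prop) + ε_add`; negative draws are re-drawn
rather than truncated (preserving the error scale; re-draws are counted and
rare at study-like parameters). `external_cohort_spec()` provides the
shorter external-validation design (25 subjects, 0–72 h schedule).

What passing tests on these cohorts show: the estimation, selection,
validation and simulation machinery is internally consistent and recovers
the generating mechanism at the study's design and noise levels. What they
cannot show: fidelity to features the generator lacks — model
misspecification of real absorption (food effects, possible lymphatic
uptake), covariate correlations (weight–sex, infection–demographics),
assay-error structure, or real dropout mechanisms. Published real-data
quantities that depend on the unreleased dataset (absolute OFV drops,
fixed-effect CV%, the printed shrinkage values) are therefore treated as
context, not as targets.

## Exposure simulation

Monte Carlo arms (defaults: 200 µg/kg, 18 mg, 36 mg; 1000 subjects per arm)
share one set of demographic and random-effect draws, so between-arm
comparisons are paired and fixed-dose linearity is exact by construction.
Residual error is off by default: exposure is summarised on model-predicted
profiles. NCA uses the linear-up/log-down trapezoid; AUC₀₋ₜ integrates to
the last grid time with concentration ≥ LLOQ on a dense grid (0.25-h steps
through absorption, hourly to 168 h) — with typical parameters the 168-h
concentration (≈3.5 ng/mL) is far above the 0.1 ng/mL LLOQ, so AUC₀₋ₜ is in
effect AUC₀₋₁₆₈. λz comes from the adjusted-R²-maximising log-linear tail
fit over at most the last 10 post-Tmax points; profiles whose tail admits no
negative slope report AUC₀₋∞ as missing rather than extrapolating.

## Problem sizes used in the checks

The test suite and acceptance script size their experiments to what the
method needs rather than to the largest possible run: exposure simulation
uses the full 1000 subjects per arm; the parameter-recovery fit uses the
full 56-subject study design; VPC calibration uses 1000 replicates on a
40-subject cohort; bootstrap and stepwise-selection experiments run at
reduced scale (10–24 subjects, 50 replicates, IIV restricted to the
dominant parameters, single-coefficient or typical-value-only refits) with
the reduction implemented through the public `estimate` control, not
through private shortcuts. The 20-replicate
recovery experiment described alongside the single-seed check is the same
call in a loop over seeds.

## Known limitations

* Single-dose oral regimens only (superposition of additional doses works,
  but multi-dose designs were never validated here); no BLQ likelihood
  methods — the emulated dataset has no fittable below-LLOQ values.
* FOCE-I only: no SAEM, no Laplace-with-interaction, no sandwich covariance
  estimator.
* The allometric reference weight and the simulated weight distribution are
  reconstructions from published summaries; per-kg-arm exposure carries that
  uncertainty.
* No inter-occasion variability, saturable elimination, enterohepatic
  recirculation, or transit-compartment absorption (the source analysis
  explored and rejected richer absorption chains).
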