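# ivmpoppk

Population pharmacokinetics of single-dose oral ivermectin (IVM), the
anthelmintic dosed at 200 µg/kg in mass drug administration (MDA) against
lymphatic filariasis. The package is aimed at pharmacometricians who want a
fully scripted, testable version of the standard Phoenix/NONMEM-style
workflow for this setting:

* **Structural model** — two-compartment disposition with linear
  elimination, fed by a depot that receives the dose as a lagged zero-order
  infusion (duration `Tk0`, lag `Tlag`) while draining at the first-order
  rate `Ka`. Solved in closed form (three-exponential), with matrix-
  exponential and ODE oracles in the tests.
* **Nonlinear mixed-effects estimation** — FOCE-I: per-subject conditional
  modes (EBEs), linearised population objective
  `OFV = Σ_i log|C_i| + r_iᵀC_i⁻¹r_i` (2π constant omitted), log-normal IIV
  with diagonal or full (log-Cholesky) Ω, combined additive + proportional
  residual error, allometric weight scaling with fixed exponents (0.75 on
  clearances, 1 on volumes) and power/exponential covariate effects.
* **Covariate selection** — stepwise forward addition (ΔOFV > 6.635,
  χ²₁ p < 0.01) and backward elimination (ΔOFV > 10.82, p < 0.001).
* **Validation** — GOF/CWRES tables (sharing the objective's linearisation),
  visual predictive checks, nonparametric bootstrap.
* **Dose-exposure simulation** — Monte Carlo cohorts under 200 µg/kg, 18 mg
  and 36 mg arms with NCA summaries (Cmax, Tmax, AUC0–t by linear-up/
  log-down trapezoid, λz-extrapolated AUC0–∞).
* **Synthetic cohorts** — a generator that emulates the study design
  (56 subjects, 57% male, weights 51–135 kg, pre-dose + 12 post-dose samples
  over 168 h, LLOQ 0.1 ng/mL), so everything runs without clinical data.

The final published model ships as `published_model()`: CL/F 7.02 L/h,
Q/F 9.11 L/h, Vc/F 138 L, Vp/F 424.33 L, Ka 0.71 1/h, Tk0 3.73 h,
Tlag 0.75 h, male sex scaling Vp/F by exp(−0.74).

## Worked example

Simulate a study-like cohort from the published model, refit it, and
simulate exposure under the three dosing arms:

```r
library(ivmpoppk)

truth <- published_model()
ds <- generate_dataset(study_cohort_spec(), truth, seed = 1)
ds
#> PK dataset 'synthetic cohort (n=56)': 56 subjects, 663 fit-eligible observations, LLOQ 0.1 ng/mL

## Monte Carlo exposure, 1000 virtual subjects per arm
cfg <- simulation_config(n_per_arm = 1000)
sim <- simulate_cohort(truth, cfg, seed = 1)
exposure_summary(cohort_exposure(sim))$by_arm[, 1:3]
#>        arm    n AUC0t_median
#> 1  fixed18 1000       2194.1
#> 2  fixed36 1000       4388.1
#> 3 perkg200 1000       1621.6
```

The medians mean: a fixed 18 mg dose gives a median AUC0–t of
2194 h·ng/mL — exactly half the 36 mg median (linear PK, paired draws) and
≈35% more than weight-based 200 µg/kg dosing in this population, the
argument for a fixed MDA dose. A full FOCE-I refit of the generated
cohort from deliberately displaced initial values (±25% typical values,
sex effect zeroed, IIV and error variances reset),

```r
m0 <- truth
m0$theta <- truth$theta * exp(0.25 * c(1, -1, 1, -1, 1, -1, 1))
m0$covariate_effects[[1]]$coefficient <- 0
diag(m0$omega) <- 0.2
m0$sigma <- c(add = 0.3, prop = 0.3)
fit <- fit_population(m0, generate_dataset(study_cohort_spec(), truth, seed = 101))
round(fit$model$theta, 2)
#>     CL      Q     Vc     Vp     Ka    Tk0   Tlag
#>   6.77   9.13 130.39 411.40   0.48   3.16   0.69
fit$model$covariate_effects[[1]]$coefficient
#> [1] -0.7125253
```

recovers the generating clearance (6.77 vs 7.02 L/h, −3.6%) and the sex
effect on Vp/F (−0.71 vs −0.74) in a few minutes.

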