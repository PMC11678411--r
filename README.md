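# gabapk

Population pharmacokinetics of gabapentin from therapeutic drug
monitoring (TDM) data.

Hospital TDM programmes accumulate sparse gabapentin concentrations —
typically one or two opportunistically timed samples per patient during
multi-dose regimens. `gabapk` turns such data into a population PK
analysis: it implements a one-compartment oral model with saturable
dose-dependent bioavailability

    F(Dose) = Dmax / (D50 + Dose),    Dmax = 823, D50 = 1120,

first-order absorption (ka fixed at 0.778 h⁻¹) and first-order
elimination, estimated as a nonlinear mixed-effects model

    log ψ_i = log ψ_pop + Σ β·log(cov_i/cov_ref) + η_i,   η_i ~ N(0, ω²),

by a hand-rolled SAEM (stochastic approximation EM) engine with
Metropolis–Hastings E-steps and closed-form M-steps. Marginal
likelihoods come from importance sampling (adaptive Gauss–Hermite
quadrature serves as the deterministic oracle in the tests), standard
errors from a common-random-numbers finite-difference Hessian.
Model building follows the clinical-question order used in practice:
renal function on clearance, body size on volume, diabetes on
absorption and volume, each covariate admitted only when an OFV drop
≥ 3.84, a Wald test at p ≤ 0.01 and an EBE-correlation test at
p ≤ 0.01 all agree, then backward deletion at ΔOFV ≥ 6.63. Validation
tools include subject-level nonparametric bootstrap, visual predictive
checks and weighted-residual diagnostics. A synthetic TDM cohort
generator reproduces the demographic and design structure of the
82-patient hospital cohort the published model was built on, so the
whole pipeline is verifiable by simulation.

## Worked example

```r
library(gabapk)

# a synthetic 82-subject TDM cohort simulated from the published model
data <- synthetic_dataset(cohort_config(), truth = final_model(), seed = 1)
data
#> pk_dataset: 82 subjects, 618 dose events, 91 observations

fit <- fit_saem(data,
                pop_model(init = c(V = 45.4, Cl = 6.31),
                          fixed = c(ka = 0.778, tlag = 0),
                          omega = c(V = 0.5, Cl = 0.3),
                          covariate_effects = list(
                            cov_effect("Cl", "SCR", beta = 0, ref = 1.3)),
                          error = error_model("constant", a = 1)),
                saem_control(), seed = 42)
round(coef(fit), 3)
#>           V          Cl beta_Cl_SCR     omega_V    omega_Cl           a
#>      39.185       5.384      -0.661       1.088       0.385       2.047
```

The fit reports the typical volume (L) and clearance (L/h), the
power-law exponent of serum creatinine on clearance, the between-subject
log-SDs of V and Cl, and the additive residual SD (µg/mL). The
generating values were 44.61, 5.73, −0.89, 0.77, 0.28 and 2.03: with 91
TDM samples across 82 subjects a single realisation scatters visibly
around the truth (here V is 12% low and the variance terms high), which
is exactly why the recovery experiment below reports medians over
replicate cohorts — and why the reference analysis leaned on bootstrap
intervals rather than point estimates alone.

Downstream steps:

```r
loglik_is(fit)                  # OFV / AIC / BIC by importance sampling
standard_errors(fit)            # RSEs via CRN finite-difference Hessian
eta_shrinkage(fit)              # eta-shrinkage per random effect
search <- covariate_search(data, saem_control(), seed = 1)
boot <- pk_bootstrap(data, search$final_model, n_rep = 200, seed = 1)
v <- vpc(search$final_fit); plot(v)
report <- run_workflow(seed = 1)   # the whole pipeline, one call
```

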