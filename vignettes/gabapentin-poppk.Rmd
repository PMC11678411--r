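---
title: "Population pharmacokinetics of gabapentin from TDM data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population pharmacokinetics of gabapentin from TDM data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gabapk)
```

## The problem

Gabapentin is renally cleared, actively absorbed by a saturable
L-amino-acid transporter, and notoriously variable between patients.
Hospital laboratories accumulate gabapentin concentrations from routine
therapeutic drug monitoring (TDM): one or two opportunistically timed
samples per patient, drawn during multi-dose in-hospital regimens. This
package implements a complete population-pharmacokinetic (popPK)
workflow for such data: a structural model, a nonlinear mixed-effects
estimation engine, a clinically ordered covariate search, and
simulation-based validation — together with a synthetic cohort generator
that emulates an 82-patient hospital TDM cohort, so every part of the
pipeline can be verified by parameter-recovery experiments.

## Structural model

Disposition is one-compartment with first-order elimination; absorption
is first-order (rate constant $k_a$, fixed at 0.778 h$^{-1}$ because
TDM sampling rarely catches the absorption phase). The absorbed
fraction is dose-dependent:

$$F(\mathrm{Dose}) = \frac{D_{max}}{D_{50} + \mathrm{Dose}},
\qquad D_{max} = 823,\; D_{50} = 1120,$$

a saturation law with constants fixed to previously published values.
With the dose in mg the ratio is dimensionless; $F$ decreases from
$D_{max}/D_{50} \approx 0.73$ at small doses to about 0.35 at 1200 mg,
reproducing the known less-than-dose-proportional exposure. The printed
units of $D_{max}$ and $D_{50}$ (mg/day) sit awkwardly beside the
definition of Dose as a single administration; we implement the ratio
exactly as written, with single-dose amounts in mg, and apply $F$ per
dose event. Concentrations are evaluated in closed form by superposition
over the recorded dosing history (mg doses and L volumes give mg/L,
identical to the reported µg/mL), with the analytic
$k_a \to k_e$ limit substituted when $|k_a - k_e|/k_a < 10^{-8}$ to
avoid catastrophic cancellation. Candidate alternatives — a fixed 0.31 h
lag and an equal-rate transit-compartment chain — are available for
structural comparison. The transit chain is evaluated through its
incomplete-gamma closed form, with numeric integration (deSolve)
retained both as a fallback for the $k_{tr} \le k_e$ corner and as the
independent oracle in the test suite.

```{r structural}
p <- structural_params(V = 44.61, Cl = 5.73, ka = 0.778)
conc_first_order(3, data.frame(time = 0, amount = 300), p)
bioavailability(c(100, 300, 1200))
```

## Statistical model

Individual parameters are log-normal around covariate-adjusted typical
values:

$$\log \psi_i = \log \psi_{pop} + \textstyle\sum_k \beta_k x_{ik} + \eta_i,
\qquad \eta_i \sim N(0, \omega^2),$$

with continuous covariates entered as $\log(c_i/c_{ref})$ — log
transformed and centred, $c_{ref}$ defaulting to the dataset arithmetic
mean — and categorical covariates as indicators against the largest
class. Random effects are diagonal and, in the final model, confined to
$V$ and $Cl$. The residual error is additive Gaussian ("constant"
model, SD $a$ in µg/mL); proportional and combined models are available
for error-model comparison. The constant model admits negative
simulated concentrations at low predictions; simulation keeps them by
default because clipping would bias the error variance downward (a
cosmetic clip is available).

The published final model (`final_model()`) carries $V$ = 44.61 L,
$Cl$ = 5.73 L/h, a power-law serum-creatinine effect on clearance
($\beta = -0.89$, centred at 1.3 mg/dL), $\omega_V$ = 0.77,
$\omega_{Cl}$ = 0.28 and $a$ = 2.03 µg/mL; it doubles as the default
generating truth of the synthetic cohort module.

## SAEM estimation

`fit_saem()` implements stochastic approximation EM:

* **E-step** — per-subject Metropolis–Hastings on the log-parameter
  vector $\phi_i$, three kernels per sweep (independent draw from the
  population law, component-wise random walk, joint random walk), with
  proposal scales adapted towards a 0.35 acceptance rate. All subjects
  are updated in one vectorised pass.
* **SA-step** — Robbins–Monro averaging of the complete-data sufficient
  statistics: step size 1 during the exploratory phase (default 300
  iterations), $1/(k - K_1)$ during smoothing (default 200).
* **M-step** — closed form: per-parameter least squares for typical
  values and covariate coefficients (fixed coefficients respected via
  restricted normal equations), moment updates for $\omega^2$, and
  $a^2 = \frac{1}{N}\sum E[(y - f)^2]$ for the constant error model.
  During burn-in the variance parameters are annealed (they may shrink
  by at most a factor 0.95 per iteration) so the chain cannot collapse
  prematurely. For the proportional and combined error models the
  M-step minimises a surrogate objective built from the SA-averaged
  per-observation squared residuals and predictions; this is exact for
  the proportional model and a standard approximation for the combined
  one.

A parameter that carries a covariate effect but no stated random effect
(the covariate-on-$k_a$ tests) is given a small fixed log-SD (0.05) so
the same linear-Gaussian machinery estimates its coefficient; the
extra variability is negligible against the residual error at the
study's scale. Identical seed, settings and data give a bit-identical
iteration trajectory.

Likelihood evaluation is separate from estimation: `loglik_is()`
computes per-subject marginal likelihoods by importance sampling with a
multivariate $t_5$ proposal centred at each subject's Laplace posterior
mode (1000 samples/subject by default, Monte-Carlo SE reported, low
effective-sample-size warnings attached), and `loglik_agq()` provides
deterministic adaptive Gauss–Hermite quadrature for up to two random
effects — used throughout the tests as the brute-force oracle, never as
the production path. OFV is $-2\log L$; AIC adds $2P$; BIC adds
$P\log N_{obs}$ with the total observation count (the mixed-effects
BIC variant that splits subject- and observation-level parameters is
deliberately not replicated). Standard errors come from a
finite-difference Hessian of the importance-sampled log-likelihood
evaluated with common random numbers, with log-scale parameters mapped
back by the delta method; a non-positive-definite information matrix
flags the affected parameters rather than fabricating SEs.

## Covariate selection

`covariate_search()` mirrors the clinical-question order: renal
indicators (SCr, CrCl, eGFR, AKI) on clearance first, body-size metrics
(WT, IBW, ABW, LBW, BMI, obesity) on volume second, diabetes-related
covariates (diagnosis, fasting glucose, combined metabolic category) on
$k_a$ and $V$ third, then a screen of everything remaining against the
random effects (correlation $p \le 0.01$). A covariate enters only if
three gates all pass: OFV drop $\ge 3.84$ ($\chi^2_1$ at 5%), Wald
$p \le 0.01$ on the fitted coefficient, and $p \le 0.01$ on the
correlation (continuous) or one-way ANOVA (categorical) test between
the base model's empirical Bayes etas and the covariate. Because the
renal indices are algebraically collinear through SCr, a stage admits
at most one winner per target parameter — the largest OFV drop, ties
resolved towards the covariate needing fewest derived inputs. Backward
deletion then removes any retained covariate whose deletion raises the
OFV by less than 6.63 ($\chi^2_1$ at 1%). Base and augmented OFVs are
evaluated with the same seed so Monte-Carlo noise largely cancels
inside the 3.84 gate.

In `run_workflow()` the structural choice follows the reference
analysis's parsimony logic rather than a raw information-criterion
ranking: the two bioavailability modes have equal complexity, so the
better OFV wins outright, while added absorption machinery (lag time,
transit chain) is adopted only on a significant improvement (OFV drop
$\ge 3.84$) over plain first-order absorption. The error model is then
chosen by BIC among constant, proportional and combined, and the
covariate search runs on the winner.

## The synthetic TDM cohort

`cohort_config()` encodes the study conditions: 82 subjects; age,
weight, height and fasting glucose truncated-normal at the published
mean, SD and range; serum creatinine log-normal moment-matched to mean
1.3 and SD 1.0 mg/dL and truncated to 0.4–3.8; 62.2% female, 7.3%
black; 31.7% diabetes; 21.9% AKI; single doses from a 100–1200 mg menu
weighted to the published median of 300 mg (weights
0.05/0.15/0.45/0.15/0.10/0.05/0.03/0.02 over
100/200/300/400/600/800/900/1200 mg — a modelling choice, configurable);
q8/q12/q24 regimens; 2–5 days of dosing history with samples drawn
uniformly inside the final dosing interval (emulating near-steady-state
TDM draws); and 1 sample per subject with probability 0.85, 2 with 0.15
(≈1.15 samples/subject, matching the cohort's 123 concentrations from
108 screened patients). Diabetic subjects draw from shifted weight
(+10 kg), glucose (+90 mg/dL) and log-creatinine (+0.15) distributions —
reflecting the reported heavier, hyperglycaemic, lower-eGFR diabetic
subgroup — with the shifts centred so the marginal moments stay at the
published values; the magnitudes are modelling choices since only the
direction of the gradient is reported. All other covariates are drawn
independently: the cohort table reports no correlation structure, and
none is invented beyond the diabetes links.

What the generator does *not* emulate: longitudinal creatinine
trajectories (AKI is a drawn flag, not a mechanism), adherence gaps or
dose changes within the history, assay quantification limits, and any
covariate correlation beyond the diabetes shifts. Recovery experiments
on these data therefore demonstrate the estimator's correctness under
the declared model, not robustness to the full messiness of hospital
records.

```{r synth}
d <- synthetic_dataset(cohort_config(n = 20), final_model(), seed = 1)
d
head(as.data.frame(d))
```

## Numerical choices and degenerate inputs

* $k_a = k_e$ degeneracy: analytic limit below a relative difference of
  $10^{-8}$.
* Transit chain with $k_{tr} \le k_e$: stable recursion for
  $\int_0^t s^n e^{-\lambda s}\,ds$ with a series branch for
  $|\lambda t| < 10^{-8}$; the incomplete-gamma form is used when
  $\lambda > 0$.
* Estimated random-effect SDs are floored at $10^{-3}$; an omega fixed
  at 0 removes the random effect entirely (the parameter leaves the
  sampled vector).
* Proposal scales are clamped to $[0.05, 20]$; MH acceptance targets
  0.35.
* VPC bins are equal-count on time since first dose (default 6); bins
  with fewer than 5 observations merge into a neighbour and are
  reported. Bin boundaries are a design choice — the reference analysis
  does not state its binning.
* The bootstrap resamples subjects (not observations), unstratified,
  refitting from the original initial values; replicates that fail are
  counted and excluded, and more than 20% failures flags the result
  unstable.
* A subject's empirical Bayes estimate falls back to the population
  covariance when the per-subject Laplace Hessian is not positive
  definite; such subjects are flagged.

## Problem sizes used in the validation suite

The recovery experiment fits 10 replicate cohorts of 100 subjects on
300 mg q8h for 48 h with samples at 1, 3, 6 and 8 h after the last dose
— a design rich enough that the median estimate across replicates pins
every parameter of the final model. The oracle batteries run on 12–20
subject problems where adaptive quadrature is exact to machine
precision. The selection-calibration experiment uses 100 null and 25
effect-bearing cohorts at the study's own 82-subject sparse design. The
end-to-end workflow check runs three seeded replicates with a reduced
bootstrap; the full 1000-replicate bootstrap of the reference analysis
is available by setting `n_boot = 1000`.

## Known limitations

* The real hospital dataset is not deposited, so the real-data OFVs
  (496.44/507.42) and the exact published estimates are not
  reproduction targets; the package validates against them only through
  simulation truth.
* At the sparse TDM design the renal indices are nearly
  interchangeable: log eGFR is essentially an affine function of log
  SCr plus weak age/sex terms, so the expected OFV advantage of the
  true covariate is of the same order as its between-replicate noise
  and stage 1 occasionally crowns CrCl or eGFR instead of SCr. This is
  a property of the design, not of the estimator; the rich recovery
  design identifies the SCr coefficient to within a few percent.
* No inter-occasion variability, no correlated random effects, no
  below-quantification-limit likelihood handling, no IV dosing.
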