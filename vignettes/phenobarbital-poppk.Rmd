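---
title: "Methods: an autoinductive population PK model of phenobarbital in dogs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an autoinductive population PK model of phenobarbital in dogs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenopk)
```

## The model

Phenobarbital in dogs is described by a one-compartment model with
first-order oral absorption and an elimination clearance that rises over
time because the drug induces its own metabolizing enzymes. The
induction is represented by an enzyme-turnover (indirect response)
mechanism in which the drug *inhibits enzyme degradation*:

$$
\begin{aligned}
\frac{dA_d}{dt} &= -k_a A_d \\
\frac{dA_c}{dt} &= k_a A_d - \frac{CL_i}{V_i}\,Enz \cdot A_c \\
\frac{dEnz}{dt} &= K_{enz} - K_{enz}\left(1 -
  \frac{C_c}{C_c + IC_{50}}\right) Enz,
\qquad C_c = A_c / V_i .
\end{aligned}
$$

Production and degradation rate constants of the enzyme pool are set
equal ($K_{enz}$), so the drug-free steady state is $Enz \equiv 1$ and
$Enz$ is a *relative* pool size. At a constant concentration the pool
equilibrates at $Enz_{ss} = 1 + C_{ss}/IC_{50}$; because the pool
multiplies the elimination rate, apparent clearance increases with
exposure and concentrations at steady state are lower than a linear
model would predict from the first days of therapy. Two printed forms
of these equations in the source literature omit the depot input term
and the $Enz$ multiplier in the degradation term; we implement the
mechanistically complete system above (a depot-driven absorption arrow
and first-order degradation are the standard turnover construction, and
they are required for the stated drug-free steady state to exist).

Two closed forms anchor the numerics. With induction disabled
($IC_{50} \to \infty$) the single-dose solution is the Bateman
equation, which the integrator must reproduce to 0.1%. Under repeated
dosing (dose $D$ every $\tau$) the steady-state mass balance is

$$
D/\tau = CL_i \left(1 + \frac{C_{ss}}{IC_{50}}\right) C_{ss},
$$

a quadratic whose positive root the 60-day ODE interval average must
match within 0.5%. Deep in induction ($C_{ss} \gg IC_{50}$) the root
grows like $\sqrt{D}$: doubling the dose raises exposure by much less
than twofold, which is why loading phases are needed to reach the
window quickly but maintenance doses saturate slowly.

## Parameters, units, defaults

Units are fixed throughout: hours, mg, L, mg/L (1 mg/L = 1 µg/mL).
All disposition parameters are apparent (confounded with oral
bioavailability $F$); doses enter the depot in full.

| parameter | meaning | default | note |
|---|---|---|---|
| `ka` | absorption rate constant, 1/h | 0.6 | fixed, literature-based (one source section prints 0.61; the parameter table's 0.6 is adopted) |
| `V_ref` | apparent volume at 20 kg, L | 20 | fixed; scales linearly with weight |
| `CL_pop` | typical CL/F at 20 kg, 5 y, L/h | 0.015 | estimated |
| `beta_wt` | allometric weight exponent | 0.75 | fixed in the final model |
| `beta_age` | age power exponent | −0.15 | estimated; clearance falls with age |
| `Kenz` | enzyme turnover rate, 1/h | 0.15 | estimated |
| `IC50` | concentration halving enzyme degradation, mg/L | 1.77 | estimated |
| `omega_CL` | SD of log-normal IIV on CL/F | 0.3 | not reported by the source study; see below |
| `sigma_add` | additive residual SD, mg/L | 2 | not reported; see below |

The covariate model on CL/F is
$CL/F = CL_{pop} (WT/20)^{3/4} (AGE/5)^{\beta_{AGE}}$, centred at the
population medians (20 kg, 5 years); sex was tested and not retained.
The study's parameter table omits the random-effect and residual-error
magnitudes, so the synthetic truth uses `omega_CL = 0.3` (≈30% CV,
typical of phenobarbital TDM populations) and `sigma_add = 2` mg/L
(≈7% of a mid-window concentration, consistent with a validated
immunoassay). Both are plainly configurable; fixed-effect recovery is
insensitive to their exact values.

## Numerical integration

The right-hand side is compiled C used through `deSolve::lsoda`
(relative tolerance 1e-8, absolute 1e-10, banded numerical Jacobian).
Doses are deSolve *events* that add to the depot state, so integration
restarts at dose times rather than smoothing through discontinuities.
Because doses enter the depot, the central concentration is continuous
at dose times and predose (trough) values can be read directly at the
dose time.

A structural observation drives the package's performance: for fixed
$k_a$, $K_{enz}$, $IC_{50}$ and a fixed dose schedule *in concentration
units* (amount/$V_i$), an individual's profile depends on the subject
only through $k_e = CL_i/V_i$. Per-kg dosing combined with linear
weight scaling of volume gives every subject the same schedule in
concentration units, so one integration of a bank of systems on a
log-$k_e$ grid (spacing 0.08, span covering every subject's random
effect to ±6 SD) plus per-time cubic splines serves all subjects,
quadrature nodes and Monte Carlo replicates. Spline queries outside the
grid — possible only ~6 prior SDs into the tail, where the integrand is
negligible — are clamped to the grid edge. Cached predictions agree
with direct per-subject solves to ~1e-8 relative error (tested), and
the same machinery simulates 1,000-dog regimen cohorts in fractions of
a second.

## Estimation

There is a single random effect, so the marginal likelihood is a
one-dimensional integral per subject. It is evaluated by *adaptive*
Gauss–Hermite quadrature: the conditional mode of each subject's
penalized log-density is located (coarse grid then golden-section
polish), the local curvature is measured by finite differences, and 32
nodes are scaled to that Gaussian approximation. This is deterministic
and exact up to quadrature error — 32 vs 64 nodes move the objective by
less than 0.01 (tested) — in contrast to the stochastic EM algorithm
used by commercial tools, and is the natural choice for a 1-D random
effect. With `omega_CL = 0` the integral degenerates to the plain
Gaussian −2 log-likelihood at $\eta = 0$.

The outer optimizer is `nlminb` (PORT) on transformed parameters: logs
for `CL_pop`, `Kenz`, `IC50`, `omega_CL`, `sigma_add`, identity for the
covariate exponents. Documented initial values are CL_pop 0.01,
Kenz 0.1, IC50 1, exponents 0, omega 0.2, sigma 1. The box constraints
are plausibility bounds, not tuning: canine phenobarbital CL/F below
1 L/h, enzyme turnover slower than ~30 min ($K_{enz} \le 2$/h), IC50
within the assay's dynamic range. The turnover bound matters: with only
trough-dominated sampling the likelihood admits a degenerate branch in
which $K_{enz} \to \infty$ (instantaneous enzyme equilibration) mimics
the steady-state data with absurd CL/IC50 values; estimates that end on
a bound are flagged with a warning so the analyst sees that the data
did not resolve the turnover timescale.

Standard errors come from the numerical Hessian of OFV/2 at the optimum
(central differences, relative step 1e-4, on the transformed scale),
inverted and delta-method mapped to the natural scale; RSE% is
100·SE/|estimate|. `bicc()` uses the hybrid mixed-effects penalty:
parameters tied to the subject-level random effect (everything on CL/F,
including its covariate exponents and `omega_CL`) are penalized by
log N_subjects, purely fixed-effect and error parameters by
log N_observations; when every subject contributes one observation this
reduces to the classical BIC. Covariate selection is forward
(ΔOFV ≥ 3.84, 1 df, plus a two-sided Wald test at 5% on the estimated
exponent) then backward (removal must cost ≥ 6.63). Thresholds are
strict `>=`: a drop of 3.83 is not accepted. Individual MAP estimation
maximizes `log p(obs | eta) + log prior` by Brent search; with no
observations (or `omega_CL = 0`) it returns the prior mode, and the MAP
`eta` is always shrunk relative to the unpenalized individual estimate.

### Identifiability under the recovery design

The parameter-recovery study fits 100 virtual dogs dosed at exactly
5 mg/kg q12h and sampled at 48, 168 and 672 h. Because every dog then
shares one dose schedule per litre, CL/F and IC50 are separated only by
the covariate-driven spread of $k_e$ and by the two pre-steady-state
samples; the Fisher information at the optimum puts their RSE in the
30–60% range (the analysis script prints it). The real clinical cohort
had veterinarian-chosen, tablet-rounded doses spanning roughly
2.5–5.5 mg/kg, which breaks this degeneracy — one reason the study's
printed RSEs are far tighter. Recovered values therefore scatter along
a CL–IC50 ridge across simulation seeds while `beta_age`,
`omega_CL` and `sigma_add` are recovered tightly. This is a property of
the design, not the estimator: with residual noise reduced tenfold, or
with more dose variation, the same code recovers the generating values
closely.

## The synthetic-data generator

The generator emulates the study's structure: ~100 dogs, 57% male, age
5.4 ± 3.5 y, weight 21.3 ± 14.0 kg, drawn from truncated normal
distributions (age 0.3–16 y, weight 2–70 kg) whose parent moments are
adjusted by moment matching so the realized mean/SD hit the targets
despite truncation. Dosing is oral, per kg, q12h, optionally rounded to
achievable tablet combinations (100/40/15 mg and halves, i.e. sums of
{100, 50, 40, 20, 15, 7.5} mg). The default *sparse* design mirrors
clinical TDM: one predose trough on a random day between day 20 and 40
(steady state), a 20% chance of a second trough; the *rich* design
(48/168/672 h) exists for identifiability of the induction dynamics.
Residual error is additive Gaussian; negative draws are truncated at
zero; observations below the 1.1 mg/L assay LLOQ are flagged, and by
default excluded from estimation (`MDV = 1`), since the study reports
no censoring model.

What the generator does *not* emulate: dose titration by the treating
veterinarian in response to measured levels (real TDM data are
feedback-confounded), co-medication, breed effects, interoccasion
variability, and assay error that scales with concentration. Passing
recovery tests on these synthetic cohorts therefore demonstrates
correctness of the estimation machinery under the stated model, not
robustness to the messiness of real clinical data.

Event tables use a NONMEM-style CSV dialect
(`ID, TIME, AMT, DV, EVID, MDV, WT, AGE, SEX` plus an optional `BLQ`
flag, `"."` for missing, `#` comment lines); numbers are written with
17 significant digits so a write/read round trip is exact. An
observation at a dose time is a predose sample and sorts before the
dose row.

## Diagnostics

*Validation metrics.* ME = mean(pred − obs) in mg/L; MRE and RMSE are
the mean and root-mean-square of the *relative* error in percent.
Overprediction is positive. The RMSE carries the square root even
though one printed source formula omits the radical — the metric's name
and its percent scale require it. Both an *a priori* mode (covariates
only, $\eta = 0$) and a *MAP-updated* mode (each subject's $\eta$
re-estimated from their own observations before predicting those same
observations) are reported; the two printed validation results in the
source disagree with each other, so the package computes both modes and
labels them, taking no side.

*NPDE.* K replicate datasets are simulated under the model;
each subject's observation vector is decorrelated with the empirical
mean and lower-Cholesky factor of its simulated covariance (marginal
standardization when a subject has a single observation), ranks of the
decorrelated observations among the decorrelated simulations are mapped
through the inverse normal, and ties are broken by seeded uniform
jitter. Under the true model the result is standard normal; the summary
reports mean, variance, a t-test and a Shapiro–Wilk p-value.

*VPC.* The simplified predose VPC bins trough observations by weight
tertile (configurable break points), overlays observed 5/50/95th
percentiles on the envelope of the same percentiles across K simulated
datasets (90% envelope by default), and optionally prediction-corrects
each observation by the ratio of its bin's median population prediction
to its own. Empty bins merge into a neighbour with a warning; `K = 1`
degenerates to a single-simulation band, which is allowed.

## Dosing simulation

Regimen plans are per-kg and stratified by weight (<10, 10–25, >25 kg)
and age (≤1, 1–7, ≥7 y). The published table does not define phase
hand-offs precisely, so the package fixes a convention: loading doses
at their stated times (a "20 mg/kg/24 h from 0 to 48 h" cell means
doses at 0 and 24 h); the progression phase starts 24 h after the last
loading dose and runs q12h for its stated 5 days; maintenance starts
when progression ends, or 24 h after the last loading dose when the
cell has no progression phase. Stratum boundaries resolve as weight
[0,10), [10,25], (25,∞) and age (0,1], (1,7), [7,∞). Within a stratum
covariates are drawn uniformly (the study's choice is unreported; the
truncated study distributions are available through the generator).
IIV uses the default `omega_CL = 0.3` and no residual error is added —
target attainment concerns true concentrations, not assay readings.

PTA is evaluated on steady-state troughs by default (predose levels are
the clinical TDM quantity throughout the source study); a
whole-interval variant requires the entire final-interval range inside
the window. Steady state is checked per subject by comparing the last
two troughs (0.1% relative). `time_to_target()` reports the first
trough time from which the trajectory stays inside 15–45 mg/L, and
`search_maintenance_dose()` walks a sorted candidate list with common
random numbers and returns the smallest dose whose PTA reaches 90%,
together with the whole dose–PTA curve — which is not monotone at the
top, because high doses start violating the 45 mg/L ceiling.

## Problem sizes and runtime choices

The test suite and scripts use sizes chosen to exercise every code path
at interactive speeds: recovery fits use 100 dogs × 3 samples
(minutes), property-level fits 10–30 dogs on a 14-day design (seconds
each), NPDE/VPC 120–150 dogs with K = 300–1000 replicates, and regimen
Monte Carlo 1,000 dogs per stratum (sub-second thanks to the log-ke
bank). The brute-force oracle for the marginal likelihood uses 20,000
Monte Carlo draws on a 3-subject toy and bounds the quadrature result
within three Monte Carlo standard errors.

## Known limitations

- One disposition compartment and a single random effect (on CL/F);
  no interoccasion variability, no omega matrix.
- `ka` and `V_ref` are fixed: sparse trough data cannot identify them.
- The CL–IC50 ridge under uniform per-kg dosing (above) is a design
  property users should expect in their own sparse datasets; richer
  dose variation or early sampling resolves it.
- The LLOQ is handled by exclusion or flagging, not by a censored
  likelihood (M3-style) contribution.
- No pharmacodynamic (seizure-outcome) or toxicity modelling beyond the
  45 mg/L ceiling.
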