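---
title: "Shape metrics and predicted steady-state bioequivalence: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape metrics and predicted steady-state bioequivalence: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pkshape)
```

## The problem

For prolonged-release oral products, absorption is slower than elimination
(flip-flop kinetics), so the terminal part of the plasma
concentration–time curve is governed by the *product*, not the subject.
Two formulations can then be bioequivalent on the conventional single-dose
metrics — Cmax, AUC~0–t~, AUC~0–inf~ — while their curves have visibly
different shapes, and that shape difference resurfaces as a non-equivalent
trough concentration once dosing reaches steady state. When the first
dosing interval covers less than 90% of AUC~0–inf~ (significant
accumulation), European regulators therefore ask for a steady-state study.

`pkshape` implements the full chain needed to study this problem on a
concrete system — desvenlafaxine 100 mg prolonged-release tablets, dosed
once daily, sampled at 21 nominal times over 72 h, LLOQ 1 ng/mL:

1. a synthetic 2×2 crossover study generator with a configurable
   formulation (curve-shape) difference,
2. non-compartmental analysis including the alternative shape metrics
   (C~τ~, paired partial AUCs, half-value duration),
3. average-bioequivalence statistics for the 2×2 crossover,
4. empirical-Bayes (MAP) individual parameter estimation under a
   population PK model,
5. superposition-based prediction of the steady-state metrics
   (AUC~0–τ~, C~max,ss~, C~τ,ss~) and their bioequivalence assessment,
6. a prediction-corrected visual predictive check.

The clinical data behind the published desvenlafaxine case are not
public; the generator stands in for them, and the published summary
tables (`desven_be_summary()`) serve as deterministic worked examples for
the confidence-interval arithmetic only.

## Structural model

The concentration after a single oral dose follows a linear chain:
the dose enters the first of `n_transit` transit compartments (each
emptying at first-order rate $k_{tr}$), the chain feeds an absorption
compartment (rate $k_a$), and the drug is eliminated from one central
compartment of apparent volume $V_1$ at $k_e = CL/V_1$. With
`n_transit = 2` this is a four-state linear system — the conventional
transit-compartment absorption model, which we adopted because it is the
standard way a chain of "two transit compartments with rate $k_{tr}$
plus absorption rate $k_a$" is parameterized in pharmacometric software;
the alternative reading (the second transit emptying directly into the
central compartment at $k_a$, three states) would leave $k_{tr}$
attached to a single transfer and is not how the field uses the term.
Bioavailability is fixed at 1 and absorbed into the apparent $CL$ and
$V_1$ (oral parameterization). Units are fixed: hours, mg, L; the model
works in mg/L and converts once to ng/mL.

In the Laplace domain the central amount has simple poles at $-k_a$ and
$-k_e$ and a pole of order $n$ at $-k_{tr}$, so the solution is an exact
mode decomposition

$$C(t) = \sum_i c_i\, t^{p_i}\, e^{-\lambda_i t},$$

with confluent terms $t^j e^{-k_{tr} t}$ from the repeated pole. All
analytic machinery (AUCs, steady-state accumulation) operates on this
representation; a compiled kernel evaluates it in the estimation hot
loop.

**Degenerate rates.** The partial fractions cancel catastrophically when
rate constants coincide. The error grows like $\varepsilon/\text{gap}^n$
around the order-$n$ pole, but only like $\varepsilon/\text{gap}$ for
the simple $k_a$/$k_e$ pair, so the guard is asymmetric: evaluation
switches to a matrix exponential of the state system when a pair
involving $k_{tr}$ comes within a relative gap of $10^{-4}$, or when
$|k_a - k_e|/\max$ falls below $10^{-7}$. A perturbation-continuity test
sweeps a rate through the switch.

**Steady state.** Under linear kinetics the steady-state interval profile
is the superposition $\sum_k C(t + k\tau)$. Each simple mode accumulates
by the geometric factor $1/(1 - e^{-\lambda\tau})$; confluent terms
$t^j e^{-\lambda t}$ accumulate through the closed-form sums
$S_m(x)=\sum_k k^m x^k$ (implemented up to $j = 3$, i.e. up to four
transit compartments). A truncated-superposition route (relative
tolerance $10^{-8}$, cap 10,000 doses) provides an independent second
route; the two agree to $10^{-8}$ and cross-validate each other in the
tests. Mass balance ties everything together: single-dose AUC~0–∞~ and
steady-state AUC~0–τ~ both equal $\text{dose}/CL$ — the identity that
links single-dose to steady-state exposure.

## Synthetic-study generator

The generator reproduces the reference design exactly: 32 completers,
2 treatments × 2 sequences × 2 periods with block randomization
(block size 2, hence 16/16 sequences), 100 mg, τ = 24 h, the 21-point
schedule, LLOQ 1.00 ng/mL. The population fixture
(`desven_population()`) carries the published typical values
($k_a = 0.0737$/h, $k_{tr} = 18.5$/h, $CL = 18.65$ L/h, $V_1 = 83.31$ L)
and variabilities: log-normal IIV (15/39/17/43% on
$k_a$/$k_{tr}$/$CL$/$V_1$, diagonal covariance), IOV per occasion
(13/27/14% on $k_a$/$k_{tr}$/$CL$; none on $V_1$), and residual error
additive on the log scale with SD 0.18. Reported percent variabilities
map to log-scale SDs as pct/100. IOV draws are independent across
parameters (no correlation structure was reported). Washout is treated
as complete; no carryover is simulated.

Observations below the LLOQ are flagged BLQ and carry no numeric value;
the records are kept in files for audit but excluded from every
analysis. The pre-dose sample is always BLQ (true concentration 0).

**The formulation effect** is a multiplicative factor on the test
product's absorption constants only ($k_a$ and/or $k_{tr}$); disposition
belongs to the subject, not the product. The shipped scenario uses
`ka_factor = 0.75` — the test product releasing at 75% of the reference
rate, a pure shape difference with identical extent of absorption. This
is a synthetic stand-in, not an estimate from the real products.

Two consequences of this scenario are worth stating plainly, because
they bound what the simulated case study can and cannot mirror of the
published one. With equal bioavailability and strictly linear PK,
slowing the rate-limiting absorption constant lowers the whole early
curve: at the typical values the test/reference ratios are roughly 82%
for Cmax, 98% for AUC~0–t~, 105% for single-dose C~τ~ and 118% for
steady-state C~τ,ss~. The published products, by contrast, combined a
shape difference with an ~11% higher extent for the test product (AUC
GMR 111.67%), which kept Cmax near 100% and pushed single-dose C~τ~ to
125.51%. An extent difference is deliberately outside this generator
(it would act through $CL$), so in the shipped scenario the steady-state
trough failure is faithfully reproduced, and C~τ,ss~ is the most
shape-sensitive metric, while single-dose Cmax *fails* rather than
passes and single-dose C~τ~ moves less than its steady-state
counterpart. Passing tests therefore demonstrate the machinery and the
trough-failure mechanism, not a quantitative replay of the published
tables.

## Non-compartmental analysis

All areas use the linear trapezoidal rule on the analyzed points, with
linear interpolation when a bound falls between samples. The analyzed
series treats the pre-dose BLQ as concentration 0 at $t = 0$ and drops
embedded BLQ points — so a profile whose 72 h sample is BLQ ends at
48 h, which is also why the terminal partial AUC is anchored at each
subject's own last measurable time.

- **Cmax/Tmax**: maximum observed value, earliest time on ties.
- **λ~z~**: log-linear least squares on the terminal subset chosen to
  maximize adjusted R² over all candidate tails of ≥ 3 points strictly
  after Tmax (the Cmax point excluded) — the convention of standard
  regulatory NCA software, configurable via `min_points`. Non-positive
  best slopes are reported non-estimable and AUC~0–inf~ stays empty,
  mirroring how a subject without estimable extrapolation is excluded.
- **C~τ~**: the 24 h observation, or linear interpolation between
  bracketing samples if τ is not sampled (e.g. when the 24 h point is
  BLQ).
- **Paired pAUCs** at cut-offs {8, 10, 12, 16, 20, 24} h share the
  boundary point, so the two segments add exactly to AUC~0–t~. The
  cut-offs are taken at their stated hours.
- **HVD**: the total time the piecewise-linear interpolant is at or
  above Cmax/2, crossings found by linear interpolation, disjoint
  excursions summed; points exactly at the threshold count as "in".
  Since only crossing times (not areas) are needed, "linear trapezoidal"
  here means linear interpolation of the crossings.

A bias worth knowing: on the reference schedule the 24/48/72 h tail is
widely spaced, and the linear trapezoid overestimates an exponential
decay there by several percent (~6% of AUC~0–inf~ at the typical
values). This is a property of the method as used in practice, not an
implementation artifact; NCA metrics converge to their model-based
counterparts as sampling density increases, which the tests verify on a
0.5 h grid.

The **accumulation screen** declares accumulation significant when mean
AUC over the first dosing interval is below 90% of mean AUC~0–inf~ for
*both* products, with a strict inequality at the boundary. At the
typical values the model gives 74.6%, so the reference regimen triggers
the steady-state requirement.

## Bioequivalence statistics

The 2×2 crossover model has fixed effects for sequence, period,
treatment and subject-within-sequence on ln(metric). Subject is treated
as fixed: for complete two-period data the treatment contrast and its
standard error are identical to the mixed-model ones, and the layout is
then exactly determined. The fit is computed in closed form through the
within-subject period differences $d_i = \ln y_{i2} - \ln y_{i1}$:
contrast $(\bar d_{RT} - \bar d_{TR})/2$, residual mean square
$s_d^2/2$ pooled within sequence, $df = n_1 + n_2 - 2$; a
design-matrix least-squares oracle confirms equality in the tests.
Subjects missing a period are dropped per metric.

From the fit: GMR $= 100 e^{\hat\delta}$, the two one-sided-tests 90%
interval $100\exp(\hat\delta \pm t_{0.95,df}\,SE)$ with
$SE = \sqrt{MSE\,(1/n_1 + 1/n_2)/2}$, and intra-subject
CV $= 100\sqrt{e^{MSE}-1}$. The decision compares the limits rounded to
two decimals against 80.00–125.00%, matching regulatory convention.
`ci_from_summary()` inverts this arithmetic from a published point
estimate and CV via $s^2 = \ln(1 + (CV/100)^2)$; with $n_1 = n_2 = 16$,
$df = 30$, it reproduces the printed 90% CI limits of the published
single-dose and steady-state tables to ±0.01 percentage points for every
row whose inputs are printed consistently (the unbalanced 31-subject
AUC~0–inf~ row and one shape-metric row carry slightly more print
rounding).

## Individual estimation and steady-state prediction

`map_fit()` computes the empirical-Bayes posterior mode for one
subject-period given the population model, minimizing

$$\sum_{obs}\frac{(\ln c_{obs}-\ln c_{pred})^2}{\sigma^2}
  + \sum_j \frac{\eta_j^2}{\omega_j^2}
  + \sum_j \frac{\kappa_j^2}{\pi_j^2}$$

over the log-scale random effects, with $\sigma$, $\omega$, $\pi$ fixed
at the supplied population values (pure EBE — no population
re-estimation). Within a single occasion $\eta$ and $\kappa$ enter only
through their sum, so the joint optimum is equivalent to one total
deviation per parameter with prior variance $\omega^2 + \pi^2$
($\omega^2$ alone for $V_1$), split afterwards in proportion to the
variances; this is exact, not an approximation. Estimation is per
subject-period, so a formulation-induced absorption difference surfaces
in the period-level $k_a$/$k_{tr}$ estimates — the property that lets
the predicted steady state differ by product within a subject.

Optimization runs a quasi-Newton search (PORT, objective tolerance
$10^{-12}$) from the zero-effect start plus four jittered starts
(deterministic seed), followed by a BFGS polish; a fit is reported
converged only if its optimum does not exceed the zero-effect
objective. $\sigma = 0$ is floored at $10^{-6}$, the interpolation
limit in which recovery of identifiable parameters is exact. BLQ
observations are excluded from the likelihood. `individual_nls()` is
the unpenalized two-stage fallback (very large prior variances), used
mainly to verify the shrinkage behavior: the weighted prior norm of the
MAP effects never exceeds the unpenalized fit's.

`predict_steady_state()` simulates the noise-free steady-state interval
for each converged estimate: AUC~0–τ~ by exact analytic integration of
the mode decomposition, C~max,ss~ as the maximum over a 0.1 h grid plus
the scheduled times (finer than any curvature the fitted rate constants
can produce; configurable), C~τ,ss~ as the model value at τ. Residual
error is deliberately absent, so the steady-state BE analysis inherits
only parameter-level variability. In the rare event that an estimate
lands with coincident rate constants, the interval AUC falls back to
the exact dose/CL identity and the profile to truncated superposition.

## Prediction-corrected VPC

`pc_vpc()` simulates replicate studies under the population model (1000
by default; no formulation covariate), bins by nominal sampling time —
all subjects share the schedule, so adaptive binning is unnecessary —
and prediction-corrects each value by the ratio of its bin's median
population prediction to the record's own population prediction (the
median-normalization form; with a single shared design the ratio is
identically 1, which a test asserts). Per bin it compares the observed
2.5th/50th/97.5th percentiles with the 95% prediction intervals of the
same percentiles across replicates. BLQ records are excluded on both
sides, so observed and simulated percentiles suffer identical censoring
and the calibration property is preserved; the all-BLQ pre-dose bin is
dropped. On self-simulated data, ~95–96% of bin-percentile observations
fall inside their intervals (the tests pool three datasets, 180 checks,
and require ≥ 90%).

## Numerical and design choices, in one place

- Superposition truncation: relative tolerance $10^{-8}$, dose cap
  10,000, explicit failure past the cap.
- Degeneracy guard: $10^{-4}$ relative gap for pairs involving
  $k_{tr}$, $10^{-7}$ for $k_a$ vs $k_e$; matrix exponential beyond.
- λ~z~ tail selection: maximize adjusted R², ≥ 3 post-Tmax points,
  Cmax excluded; ties resolved toward the longer tail.
- BE decision on CI limits rounded to 2 decimals; GMR itself unrounded.
- RNG: every simulating function takes a seed; one seeded stream is
  consumed in a fixed documented order (sequence blocks, then IIV, then
  per-occasion IOV, then residuals subject-by-subject), so identical
  configuration + seed reproduces a study bitwise.
- Problem sizes in the shipped tests: 50 ODE-oracle draws, 100 random
  NCA profiles, 100 random crossover datasets, 200 simulated subjects
  for MAP recovery, 200 replicate case studies, 3 × 500-replicate VPCs —
  sizes at which the Monte-Carlo error is comfortably below every
  asserted margin.

## What the synthetic study does not emulate

Dropout (the real study enrolled 36 and analyzed 32 completers),
food-effect arms, actual (vs nominal) sampling times, carryover,
subject-specific residual error, extent-of-absorption differences
between products, and any nonlinearity in absorption or elimination.
Consequently the package's simulated GMRs and CVs characterize the
shipped scenario, not the published products; only the CI
reconstruction from the published summary rows touches the real data,
and only through their printed summaries.

## A worked run

```{r case-study, eval = FALSE}
report <- run_case_study(case_study_config(), seed = 1)
report
write_report(report, "case-study-seed1")
```
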