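# pkshape

Shape-sensitive pharmacokinetic metrics and model-predicted steady-state
bioequivalence for prolonged-release oral products.

## The problem

Prolonged-release formulations absorb more slowly than they eliminate
(flip-flop kinetics), so the terminal part of the plasma
concentration–time curve is controlled by the product. Two formulations
can then pass a single-dose bioequivalence study on the conventional
metrics — Cmax, AUC<sub>0–t</sub>, AUC<sub>0–inf</sub> — while their
curve *shapes* differ enough that the trough concentration at steady
state (C<sub>τ,ss</sub>) is not equivalent. When accumulation is
significant (first-interval AUC < 90% of AUC<sub>0–inf</sub> for both
products), that failure matters clinically and regulatorily.

`pkshape` is for pharmacometricians and biostatisticians who want to
study — by simulation and by model-based prediction — whether
alternative single-dose metrics (the interval-end concentration
C<sub>τ</sub>, paired partial AUCs split at a cut-off, the half-value
duration HVD) anticipate a steady-state failure that Cmax and the AUCs
miss. It implements, end to end:

- **Structural model**: one-compartment disposition with a
  transit-compartment absorption chain (dose → *n* transits at rate
  k<sub>tr</sub> → absorption compartment at rate k<sub>a</sub> →
  central, k<sub>e</sub> = CL/V<sub>1</sub>), solved in closed form as a
  sum of exponential modes with confluent terms for the repeated transit
  pole, plus a matrix-exponential fallback for coincident rates.
  Steady state comes from per-mode geometric accumulation factors
  1/(1 − e<sup>−λτ</sup>), cross-validated against truncated
  superposition. Mass balance: AUC<sub>0–∞</sub> =
  AUC<sub>0–τ,ss</sub> = dose/CL.
- **Synthetic study generator**: 2×2 crossover with block-randomized
  sequences, exponential inter-individual and inter-occasion
  variability, lognormal residual error, LLOQ censoring, and a
  configurable test-product absorption factor — defaults emulate a
  published desvenlafaxine 100 mg prolonged-release study design
  (32 completers, 100 mg q24h, 21 sampling times to 72 h, LLOQ
  1 ng/mL).
- **NCA**: linear trapezoidal AUCs, Cmax/Tmax, adjusted-R² terminal
  slope selection, AUC<sub>0–inf</sub>, C<sub>τ</sub>, exactly additive
  pAUC pairs at arbitrary cut-offs, HVD, and the accumulation screen.
- **BE statistics**: the standard log-scale crossover model
  (GMR = 100·e<sup>δ̂</sup>, two one-sided-tests 90% CI with
  t<sub>0.95,n₁+n₂−2</sub>, intra-subject CV = 100·√(e<sup>MSE</sup>−1),
  80.00–125.00% decision), plus `ci_from_summary()` to reconstruct a CI
  from a published point estimate and CV.
- **Empirical-Bayes estimation** (`map_fit`) of individual parameters
  per subject-period, and **steady-state prediction**
  (`predict_steady_state`) of AUC<sub>0–τ</sub>, C<sub>max,ss</sub>,
  C<sub>τ,ss</sub> from the fitted parameters, noise-free.
- **pc-VPC** (`pc_vpc`): prediction-corrected visual predictive check
  with per-bin percentile prediction intervals.

`run_case_study()` chains all of it into one reproducible report.

## Worked example

```r
library(pkshape)
report <- run_case_study(case_study_config(), seed = 1)
report
```

```
Case study (seed 1, n = 32)
Accumulation: AUC interval/AUCinf = 0.71 (R), 0.62 (T) -> significant

Single dose, conventional metrics:
     metric     pe    lo     hi    cv df  pass  n
1      cmax  83.00 76.77  89.74 18.54 30 FALSE 32
2   auc_0_t 100.70 94.63 107.15 14.72 30  TRUE 32
3 auc_0_inf 101.96 95.92 108.39 14.48 30  TRUE 32

Single dose, shape metrics:
      metric     pe     lo     hi    cv df  pass  n
1      c_tau 115.74 103.81 129.05 26.07 30 FALSE 32
...
14       hvd 115.86  98.50 136.27 39.68 30 FALSE 32

Predicted steady state (64/64 fits converged):
     metric     pe     lo     hi    cv df  pass  n
1 auc_0_tau 102.58  97.29 108.16 12.52 30  TRUE 32
2   cmax_ss  95.13  90.72  99.75 11.22 30  TRUE 32
3  c_tau_ss 122.25 112.09 133.32 20.66 30 FALSE 32
```

Reading it: each row is one metric's average-bioequivalence assessment —
the geometric mean ratio test/reference in percent (`pe`), its 90%
confidence interval (`lo`, `hi`), the intra-subject CV, and the
80.00–125.00% decision. In this simulated scenario (the test product
absorbing at 75% of the reference rate, identical extent), accumulation
is significant, the AUCs pass after a single dose, and the predicted
steady-state trough C<sub>τ,ss</sub> fails (GMR 122%, CI above 125%) —
the failure the single-dose shape metrics (C<sub>τ</sub>, terminal
pAUCs, HVD) flag while the AUCs do not. Because the scenario changes
only the absorption *rate*, single-dose Cmax drops with it; see the
methods vignette (`vignettes/pkshape-methods.Rmd`) for why that differs
from a real product pair whose extent also differs.

The confidence-interval arithmetic itself can be checked against the
published desvenlafaxine summary rows:

```r
ci_from_summary(pe = 97.29, cv = 19.21, n1 = 16, n2 = 16)
#>        lo        hi
#>  89.74054 105.47457   # printed: 89.74, 105.48
```

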