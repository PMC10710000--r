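# mprselect

Penalized variable selection for **Weibull multi-parameter regression (MPR)
survival models** — parametric hazard models in which covariates act on both
the scale *and* the shape of the hazard:

```
h(t | tau_i, gamma_i) = tau_i * gamma_i * t^(gamma_i - 1)
log(tau_i)   = x_i' beta      (overall hazard level)
log(gamma_i) = z_i' alpha     (time evolution of the hazard)
```

Classical survival regression (Cox, Weibull PH) has a single regression
component and forces proportional hazards; the MPR model makes PH a testable
special case (all non-intercept `alpha` equal to zero) and yields
time-varying hazard ratios
`exp(b1 + a1) * t^(gamma_ref * (exp(a1) - 1))` otherwise.  The package is
aimed at biostatisticians fitting parametric survival models who need
principled, simultaneous variable selection in both components.

## What it implements

* **Penalized likelihood** `l0(theta) - n * sum_j J_lambda_j(|theta_j|)`
  with LASSO, SCAD (`a = 3.7`) and adaptive-LASSO penalties, one shared or
  two component-specific tuning parameters, unpenalized intercepts, and
  internal covariate standardization (results reported on the original
  scale).
* **Smoothed-penalty Newton-Raphson**: `|x|` is replaced by
  `sqrt(x^2 + eps^2) - eps` (`eps = 1e-4`) so the analytic score and block
  information matrix drive the optimization (compiled core in C++).
* **Sandwich covariance** `I^-1 I0 I^-1` for post-selection standard errors,
  reducing to the inverse observed information at `lambda = 0`.
* **BIC tuning with effective degrees of freedom**
  `df = tr(I^-1 I0)`, minimized over the tuning box by a hand-rolled
  **differential evolution** optimizer (rand/1/bin; the BIC surface is
  multi-modal), with a grid-search fallback that also emits the BIC surface
  table.
* **A simulation engine** reproducing the reference study design (AR(1)
  correlated standard-normal covariates, Weibull event times by inversion,
  uniform censoring calibrated to a target proportion) and its metrics:
  C / IC / PT / covariate-weighted MSE per component, and per-coefficient
  mean, SE, SEE and 95% coverage, with unpenalized and oracle benchmarks.

## Worked example

```r
library(mprselect)
sc  <- mpr_scenario(n = 500, seed = 42)   # the reference simulation design
d   <- mpr_simulate(sc, seed = 42)
fit <- mpr(survival::Surv(time, status) ~ x1 + x2 + x3 + x4 + x5 +
             x6 + x7 + x8 + x9 + x10,
           data = d, penalty = "alasso", structure = "separate",
           de = de_control(seed = 7))
fit
```

```
Weibull MPR model (alasso penalty, separate tuning), n = 500
  lambda = 0.0058, 0.0140
  log-likelihood -515.6419, effective df 8.06, BIC 1081.3850

Scale (beta):
(Intercept)          x1          x2          x3          x4          x5
    -1.3469     -0.8976      0.0000      0.0000      0.0000      0.0002
         x6          x7          x8          x9         x10
     0.0000     -0.7352      0.4734      0.0000      0.0000
Shape (alpha):
(Intercept)          x1          x2          x3          x4          x5
     0.4590      0.3764      0.0001     -0.0002      0.0000      0.3415
         x6          x7          x8          x9         x10
    -0.1519      0.0000      0.0000      0.0000      0.0000

Selected: 3/10 scale, 3/10 shape covariates
```

The BIC-tuned adaptive LASSO recovers exactly the true support of the
generator (`x1, x7, x8` in the scale; `x1, x5, x6` in the shape — the truth
is `beta = (-1.5, -1, 0, 0, 0, 0, 0, -0.8, 0.5, 0, 0)`,
`alpha = (0.5, 0.4, 0, 0, 0, 0.4, -0.2, 0, 0, 0, 0)`), with the selected
tuning parameters and the effective model complexity (8.06 of 22 possible
df) shown in the header.  Because `x1` has a non-zero shape coefficient its
hazard ratio is time-varying:

```r
hazard_ratio(fit, "x1", t = 1)
#> [1] 0.5937622
```

i.e. at `t = 1` a one-unit increase in `x1` carries about 0.59 times the
hazard.  `summary(fit)` adds sandwich standard errors, Wald tests and
selection flags; `predict()` gives per-subject `tau`, `gamma`, hazard,
cumulative hazard and survival; `km_log_cumhaz()` provides the Kaplan-Meier
`(log t, log H(t))` points whose straight-line shape (slope = shape
parameter) checks Weibull adequacy.

Replicated studies:

```r
rep <- mpr_sim_study(mpr_scenario(n = 1000, seed = 1),
                     penalties = list(list(family = "alasso",
                                           structure = "separate")),
                     n_replicates = 100)
rep$selection   # C / IC / PT / MSE per component, incl. benchmarks
rep$inference   # per-coefficient mean, SE, SEE, CP
```

File-based drivers (`mpr_run_fit`, `mpr_run_simulate`, `mpr_run_diagnose`)
accept JSON run configurations and write delimited-text reports; a thin CLI
lives in `inst/scripts/mprselect-cli.R`.

## Acceptance script

`scripts/acceptance.R` re-runs the desk-scale reproduction of the reference
simulation study from scratch against the installed package: it simulates
the stated design, tunes and fits the adaptive LASSO (two tuning
parameters, n = 1000), SCAD and LASSO (single tuning parameter, n = 1000)
and the adaptive LASSO (single tuning, n = 500) over 100 seeded replicates
each, aggregates the selection and inference metrics, and writes them as
JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

Runtime is roughly 15 minutes on one CPU.
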