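# spanel

Fixed-effects spatial panel models for ecological health outcomes.

## The problem

Ecological regressions of regional health outcomes — the motivating case is
the log infant mortality rate (IMR) observed for thousands of Brazilian
municipality-like units over three census periods — violate the independence
assumption of ordinary panel estimators twice over: unobserved
region-specific conditions shift every period's outcome (spatial
heterogeneity), and neighbouring regions influence each other through
spillovers or spatially correlated omitted variables (spatial dependence).
Ignoring either produces biased or inefficient coefficients and misleading
inference about the covariates policy cares about (health-care provision,
water and sanitation access, income, education).

`spanel` implements the full modelling ladder for this situation, for
analysts working with areal panel data:

1. **Pooled OLS**: `y_t = α + X_t β + ε_t`.
2. **Fixed effects (within estimator)**: `y_t = X_t β + μ + ε_t`, estimated
   by demeaning each region over time; `α` and the `μ_i` (normalized to sum
   to zero) are recovered afterwards.
3. **Spatial-error model (SEA)**: `y_t = α + X_t β + μ + φ_t`, with
   `φ_t = ρ W φ_t + ε_t`, estimated by maximum likelihood with an iterative
   two-stage procedure on the demeaned data.
4. **Spatial-lag model (SAR)**: `y_t = δ W y_t + X_t β + μ + ε_t`, by
   maximum likelihood with a concentrated likelihood in `δ`.

`W` is a row-standardized binary contiguity matrix, so `W x` is the average
of `x` over each region's neighbours; the same operator supplies spatially
lagged covariates (`W*x` columns) for spillover effects.  The
log-determinant `ln|I − ρW|` in the likelihoods is evaluated through the
cached eigenvalues of `W`.  Model selection between (2) and (3)/(4) follows
the Lagrange-multiplier battery (LM-lag, LM-error, robust variants) applied
to the least-squares residuals, and a first-difference specification with
initial-period regressors reads the effect of initial conditions on the
subsequent change in the outcome.

Because census aggregates cannot be redistributed, the package ships a
synthetic municipality-panel generator whose defaults reproduce the
structure of the motivating application: a 20 × 20 lattice (or a
"MCA-scale" 3,659-unit map), T = 3 periods, spatially smooth covariates
with realistic period drifts, region effects, and SEA or SAR disturbances
with known parameters (defaults ρ = 0.786, δ = 0.7789).

## Worked example

```r
library(spanel)
w   <- row_standardize(build_lattice_weights(20, 20))   # N = 400 regions
cfg <- synthetic_config(process = "sea", seed = 42)     # true rho = 0.786
sim <- simulate_panel(cfg, w)
fit <- fit_fe_sea(sim$panel, w)
print(fit)
```

```
Fixed effects spatial error (ML) 
             Estimate Std.Error      z Pr(>|z|)    
pub_hospit    -0.0009    0.0240  -0.04 9.70e-01    
priv_hospit   -0.1816    0.0667  -2.72 6.52e-03 ***
water_access  -0.2785    0.0257 -10.84 2.33e-27 ***
sanitation    -0.2100    0.0217  -9.68 3.55e-22 ***
rho = 0.7549 (se 0.0263) ***
sigma2 = 0.0136  R2 = 0.2525  corr2 = 0.6561
loglik = 762.35  AIC = -1512.70  N = 1200
```

The estimated spatial autocorrelation 0.755 sits about one standard error
from the generator's true ρ = 0.786, and the water and sanitation
coefficients recover their true values (−0.259 and −0.222) within sampling
noise.  The diagnostics that motivate the spatial model come from the
fixed-effects residuals:

```r
fe <- fe_ols(sim$panel)
lm_tests(fe, sim$panel, w)
```

```
LM spatial-dependence tests (fixed-effects residuals)
  lm_lag              346.558  p = 2.381e-77 ***
  lm_lag_robust         0.158  p = 0.6909 
  lm_error            397.191  p = 2.252e-88 ***
  lm_error_robust      50.791  p = 1.028e-12 ***
  spatial model warranted (both plain tests, 5%): TRUE
```

Both plain LM tests reject, so a spatial specification is warranted; the
robust pair points at the error form — exactly the structure this panel was
generated with.

A file-based pipeline (`run_models()` on a CSV + GAL pair, configured by
JSON) writes a machine-readable `results.json` and a `report.txt`
regression table; `inst/cli/spanel.R` exposes `run` and `simulate`
subcommands for shell use.

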