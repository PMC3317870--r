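---
title: "Methods: fixed-effects spatial panel models in spanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fixed-effects spatial panel models in spanel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spanel)
```

## The models

`spanel` estimates panel regressions for N areal units observed over T
periods where both regional heterogeneity and spatial dependence are
present.  Data are stacked period-major (all N regions of period 1, then
period 2, ...), so every per-period spatial operation is the block-diagonal
matrix `I_T ⊗ W`.

The ladder of specifications is

* pooled: `y_t = α + X_t β + ε_t`;
* fixed effects: `y_t = X_t β + μ + ε_t`, one intercept per region;
* spatial error (SEA): `y_t = α + X_t β + μ + φ_t`, `φ_t = ρ W φ_t + ε_t`;
* spatial lag (SAR): `y_t = δ W y_t + X_t β + μ + ε_t`;

with `ε_t` white noise of variance σ².  `W` is a binary contiguity matrix,
row-standardized so that `W x` is the neighbour average; spatially lagged
covariates `W*x` may be appended to `X` to capture spillovers of observable
conditions, which keeps the spatial-error and spatial-lag estimands
unchanged.  A random-effects treatment of `μ` is deliberately out of scope:
when the areal units exhaust the population (every municipality of a
country), the fixed-effects view is the appropriate one.

Assumptions worth stating explicitly: the panel is balanced; the weight
matrix is constant over time; the contiguity relation is symmetric before
standardization; covariates are exogenous (no instrumenting is provided);
and the disturbances are homoscedastic — a Breusch-Pagan check on the
residuals is part of the toolkit.

## Estimation

**Within transformation.**  Fixed effects are removed by subtracting each
region's time mean from the outcome and every covariate.  The region means
are retained, and after any fit the constant and effects are recovered as
`α̂ = ȳ − x̄'β̂` (grand means) and `μ̂_i = ȳ_i − x̄_i'β̂ − α̂`, which makes
`Σ μ̂_i = 0` the normalization.  Any other normalization only shifts `α̂`.
The transformation is idempotent and the within estimator is identical to
least squares with region dummies (LSDV), which the test suite asserts to
1e-10.

**Spatial error.**  On the demeaned data the Gaussian log-likelihood
concentrates, for given ρ, into a spatially filtered least-squares problem.
Estimation alternates two stages: given ρ, regress `(I − ρW) y*` on
`(I − ρW) X*` to get β; given β, maximize

```
L(ρ) = −(NT/2) ln( e(ρ)'e(ρ) / NT ) + T Σ_i ln(1 − ρ λ_i),
e(ρ) = (I − ρW)(y* − X*β),
```

over ρ by derivative-free bounded scalar optimization
(`stats::optimize`, a Brent-style bracketing method, inner tolerance
1e-10).  The loop stops when successive ρ iterates differ by less than
`tol` (default 1e-8, cap 100 iterations; on failure an error carrying the
iterate trace is raised).  The iteration starts at ρ = 0 — the
fixed-effects model is the natural null, and with ρ fixed at 0 the fit
reproduces the within estimator exactly.  At a fixed point, β is the
generalized-least-squares solution at ρ̂ and ρ̂ is a stationary point of the
fully profiled likelihood, so the result coincides with a direct profile
maximization; the tests verify agreement with a 1e-4-step grid search.

**Spatial lag.**  Here the likelihood concentrates in closed form through
two auxiliary regressions of `y*` and `W y*` on `X*` with residuals `e_0`
and `e_d`:

```
L(δ) = −(NT/2) ln( (e_0 − δ e_d)'(e_0 − δ e_d) / NT ) + T Σ_i ln(1 − δ λ_i),
```

maximized by a single bounded scalar optimization, after which
`β̂ = b_0 − δ̂ b_d`.

**Log-determinant.**  `T ln|I − ρW|` is evaluated as
`T Σ ln(1 − ρ λ_i)` from the eigenvalues of the row-standardized `W`.
Because `D^{-1} A` is similar to the symmetric `D^{-1/2} A D^{-1/2}`, the
spectrum is real and is computed once with a symmetric eigensolver, then
cached on the weights object.  The admissible interval for ρ or δ is
`(1/λ_min + 1e-6, 1 − 1e-6)`; an estimate within 1e-5 of a bound triggers a
warning.  The tests confirm agreement with dense LU log-determinants to
1e-9 on lattices up to 10 × 10.

## Variances and reported statistics

The reported disturbance variance follows the `σ̂² = e'e / NT` maximum-
likelihood convention of the classic spatial-panel routines, and no
bias correction of `σ̂²` is applied by default (an effective-sample variant
is stored alongside as `sigma2_df`).  Standard errors are a different
matter: demeaning leaves only `N(T−1)` independent observations, and an
information matrix scaled with `NT` understates uncertainty by the factor
`(T−1)/T` — enough to push nominal 95% intervals to roughly 89% coverage at
T = 3.  `spanel` therefore computes the information matrix (and the
numerical-Hessian fallback) on the effective sample by default
(`df_adjust = TRUE` in `spatial_ml_settings()`); the Monte-Carlo coverage
checks in the test suite run under this default.  Setting
`df_adjust = FALSE` restores the raw-`NT` scaling.

For the error model the information matrix is block-diagonal between β and
(ρ, σ²), with `Var(β̂) = σ̃² (X̃'X̃)^{-1}` at the filtered design; the
(ρ, σ²) block uses the trace terms `tr(G)`, `tr(G²)` (from the spectrum)
and `tr(G'G)` (dense, `G = W(I − ρW)^{-1}`).  For the lag model the full
(β, δ, σ²) information matrix is inverted, including the
`(I_T ⊗ G) X*β̂` cross terms.  The `numerical_hessian` option instead
differentiates the concentrated likelihood — useful at large N where the
dense `G` is costly.

Reported fit statistics: `R²` on the estimation (within) scale, computed
from the unfiltered mean-model residuals; `corr²` as the squared Pearson
correlation of observed and fitted outcomes on the original scale (fitted
values use `α̂ + μ̂_i + x'β̂`, plus `δ̂ (Wy)` for the lag model);
`AIC = −2 logL + 2k` with `k = K + 1 (spatial parameter) + 1 (σ²)`, the
fixed effects being concentrated out.  Because the literature is split on
including the `(NT/2) ln 2π` constant in reported log-likelihoods, both
conventions are stored (`loglik`, `loglik_no_constant`); comparisons inside
the package always use the same convention, so likelihood-ratio ordering
(`logL(SEA) ≥ logL(FE)`, likewise SAR) holds by construction and is
asserted on every test dataset.

## Diagnostics

The LM battery applies the standard cross-sectional score statistics with
the panel operator `I_T ⊗ W`:

```
LM_err = [e'(I_T⊗W)e / σ̂²]² / C,        C = T_eff · tr(W'W + WW),
LM_lag = [e'(I_T⊗W)y / σ̂²]² / J,        J = (WXβ̂)' M (WXβ̂)/σ̂² + C,
```

`M` the annihilator of the regression design, with the usual robust
adjustments; the decomposition identity
`LM_lag + RLM_err = LM_err + RLM_lag` is asserted to 1e-8.  One choice
deserves emphasis: for pooled residuals `T_eff = T`, but for within-demeaned
residuals the demeaning projection `Q = I_T − J_T/T` has trace `T − 1`, and
the variance of the quadratic form `e'(Q⊗W)e` involves
`(T−1) tr(W'W + WW)`.  Using `T` there would shrink the statistic by
`(T−1)/T` and collapse the empirical size from 5% to under 2% at T = 3, so
`spanel` uses `T_eff = T − 1` on fixed-effects residuals.  The size
simulations in the test suite (1000 independent panels, N = 100, T = 3)
confirm all four tests hold the 5% level within [3.5%, 6.5%] under this
convention, with LM-error power above 90% against ρ = 0.7.

When both plain tests reject on the least-squares residuals, the battery
sets `spatial_model_warranted = TRUE` — the decision rule that sends the
analyst up the ladder to the spatial specifications.  Both pooled and
fixed-effects residuals are diagnosed, mirroring the two columns of the
usual reporting layout.

The homoscedasticity check is Koenker's studentized Breusch-Pagan statistic
(`n R²` of the auxiliary regression of squared residuals on the
covariates), cross-checked in the tests against an independent
implementation; for the spatial-error model it is applied to the spatially
filtered (whitened) residuals.

## The first-difference specification

`build_first_difference()` redefines the outcome as `Δy_t = y_t − y_{t−1}`
while the regressors enter at their period `t−1` values, copied verbatim
(not differenced) — they are initial conditions, not contemporaneous
controls.  With T = 3 input periods the differenced panel has exactly 2
periods, the minimum for a fixed-effects fit; the same FE/SEA/SAR machinery
then applies, each region effect absorbing one difference.  Low within
variation is the price of that design and is visible in wider standard
errors.  `sign_flip_interpretation()` tabulates sign reversals between the
level and difference fits; under convergence dynamics (largest gains where
initial conditions are worst) the difference coefficients systematically
oppose the level ones, which the tests reproduce with a purpose-built DGP
and refute under a null DGP without convergence.

## The synthetic generator

`synthetic_config()` describes the data-generating process; its defaults
are the study conditions the package is validated under, not tuning knobs:

* 20 × 20 rook lattice (N = 400), T = 3 periods labelled 1980/1991/2000;
  a `mca_scale` preset switches to 61 × 60 trimmed to 3,659 units, the
  size of the Minimum Comparable Area map, giving 10,977 level rows and
  7,318 first-difference rows.
* true β = (−0.048, −0.166, −0.259, −0.222) for public and private
  health-care institutions per 1,000 people, water access and sanitation
  access — the fitted spatial-error coefficients of the motivating
  application.
* ρ = 0.786 (SEA) or δ = 0.7789 (SAR); σ_ε = 0.14, matching the reported
  disturbance variance of about 0.0194; σ_μ = 0.15, chosen so the regional
  heterogeneity is of the same order as the within-period outcome spread
  (sd ≈ 0.21 on the log scale).
* covariate period means and sds follow the published descriptive table
  (water access rising 0.24 → 0.43 → 0.63, sanitation 0.11 → 0.30, and so
  on); fields are spatially smoothed as `x = (I − κW)^{-1} u` with
  κ = 0.5 and rescaled to hit those targets exactly.

Covariates share the disturbance `W` by default (a flag decouples them for
robustness checks), and a `mu_covariate_corr` flag correlates the fixed
effects with the first covariate's regional mean to create the
pooled-versus-FE contrast seen in real panels.

`imr_preset()` additionally solves period-specific intercepts
`α_t = target_t − x̄_t'β` so that the expected period means of the simulated
log outcome equal the observed descriptive means (1.89, 1.64, 1.46).  The
covariate drifts with the configured β explain only about 0.16 of the
observed 0.43 decline, so the intercepts absorb the secular improvement
(vaccination, primary care, education) not carried by the four covariates.
The preset is analytic, hence idempotent under re-application.

What the generator does **not** emulate: zero-inflation and boundedness of
share-type covariates (Gaussian fields can stray outside [0, 1]),
census sampling weights, under-reporting of deaths, irregular polygon
geometry (lattice contiguity stands in for the municipal map), and
endogenous covariates.  Passing tests therefore demonstrate estimator
correctness under the assumed model, not robustness to those features of
real data.

The generator doubles as its own oracle: the spatial systems are solved by
sparse LU, and the tests confirm agreement with a 50-term Neumann series
`Σ ρ^k W^k` to 1e-6 for |ρ| ≤ 0.5, plus the qualitative signatures of the
error process (variance amplification, positive Moran-type quadratic
forms).

## Numerical choices and degenerate inputs

* Islands (zero-neighbour units) are kept with an all-zero row and a
  warning — dropping them would unbalance the panel; their spatial lag is 0
  and their spectrum contribution is the eigenvalue 0.
* Contiguity is binary before standardization; no distance decay.  Rook is
  the default criterion with queen available — on an irregular municipal
  map the choice is an empirical question, so it is a configuration knob.
* The outcome log transform defaults to the natural logarithm, with a
  `base` option (descriptive tables of log-IMR are often base-10).
* Significance stars use thresholds 1/5/10% inclusive: a p-value of exactly
  0.05 maps to `**`.
* Rank-deficient designs, time-invariant covariates (zero within
  variance), unbalanced or duplicated panel rows, nonpositive outcomes
  before the log, dangling or asymmetric GAL entries all raise errors
  naming the offending columns, rows or lines.
* Constant residuals make the Breusch-Pagan check degenerate; it returns
  statistic 0 and p = 1 rather than dividing by zero.

Problem sizes used by the validation suite, chosen to give tight
Monte-Carlo error at interactive runtimes: oracle comparisons at N = 49–100;
parameter recovery over 200 simulated panels at N = 400, T = 3 (both
processes), checking means within 3 Monte-Carlo standard errors and 95%
Wald coverage within [90%, 99%]; LM size over 1000 panels at N = 100;
structural checks of the 3,659-unit preset run at full size but without the
(optional, minutes-long) dense-spectrum ML fit.

## Known limitations

Only balanced panels are supported.  The estimators assume a time-constant
`W` and exogenous regressors; no GMM/IV or dynamic-panel variants are
provided.  The spatial Durbin case is covered only implicitly, by adding
`W*x` columns as regressors.  Inference on the recovered `μ̂_i` is not
provided (they are incidental parameters).  At several thousand units the
analytic information matrix requires a dense `N × N` solve; use
`se_method = "numerical_hessian"` there.
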