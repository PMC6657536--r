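---
title: "Modelling platelet aggregation kinetics as functional data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling platelet aggregation kinetics as functional data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plateletfda)
```

## The problem

Light-transmission aggregometry measures percent platelet aggregation in
platelet-rich plasma continuously for roughly 6–7 minutes after an agonist
(here ADP) is added. The trace shape carries the kinetics: with increasing
ADP dose the initial rise gets steeper and higher; at low doses unstable
micro-aggregates dissociate again (de-aggregation, a decline after the
initial rise); at intermediate doses traces show fluctuations and plateau
("staircase") phases; gold nanoparticles added near a critical ADP dose
enhance aggregation. Classical analyses compress a trace into one number.
This package models the whole trace, its derivatives, and the empirical
differential equation the trajectory obeys.

## The smoothing model

A single-condition trace set is modelled as $y_i(t) = f(t) + \epsilon_{it}$
with $f$ smooth (twice continuously differentiable) and
$\epsilon_{it} \sim N(0, \sigma_\epsilon^2)$ independent. $f$ is represented
in the truncated power basis

$$f(t) = \sum_{j=0}^{p} \beta_j t^j + \sum_{k=1}^{K} u_k (t-\kappa_k)_+^p,
\qquad (x)_+^p = \begin{cases} x^p & x > 0 \\ 0 & x \le 0,\end{cases}$$

with $\kappa_1 < \dots < \kappa_K$ knots strictly inside the observed time
range. Treating $u_k \sim N(0, \sigma_u^2)$ as random effects penalizes the
contribution of each truncated basis function and makes the model a linear
mixed model: the smoothing parameter $\lambda =
\sigma_\epsilon^2/\sigma_u^2$ is estimated by REML (ML available via
`method = "ML"`), and $(\hat\beta, \hat u)$ are the BLUP solution of the
mixed-model equations, equivalently the generalized-ridge solution
$(C'C + \lambda D)^{-1}C'y$ with $D$ penalizing only the truncated block.
The basis is linear in its coefficients, so the velocity and acceleration
estimates are the exact calculus derivatives of the fitted basis applied to
the same coefficients:

$$\hat f^{(m)}(t) = \sum_{j \ge m} \hat\beta_j \tfrac{j!}{(j-m)!} t^{j-m} +
\sum_k \hat u_k \tfrac{p!}{(p-m)!} (t-\kappa_k)_+^{p-m}, \quad m = 1, 2.$$

### Assumptions

* Additive, homoscedastic, independent Gaussian noise within a trace. The
  estimators are not designed for heteroscedastic or heavily autocorrelated
  noise; the generator offers an AR(1) knob (off by default) precisely so
  that robustness to mild autocorrelation can be probed.
* Traces pooled within a condition share one mean curve; there is no
  subject-level random effect. Replicate traces are treated as replicate
  observations of the same $f$.
* No shape constraints: the curve is free to rise, fall and oscillate.

### Tunable parameters

* `degree` (default 5): piecewise-polynomial degree. Degree 5 keeps the
  second derivative (acceleration) a cubic spline, i.e. smooth across
  knots; degree $p$ supports derivative orders up to $p-1$, and the package
  exposes orders 0–2.
* `knots` (default `"auto"`): $K = \min(\lfloor n_\mathrm{distinct}/4
  \rfloor, 35)$ knots at interior quantiles of the distinct observed times
  — the usual penalized-spline practice of supplying ample knots and
  letting $\lambda$ do the smoothing. The aggregometer's sampling interval
  is instrument-specific; the generator's default grid of $L = 400$ points
  over 7 minutes is a deliberate, documented guess at dense optical
  sampling.
* `lambda` (default: REML-estimated): may be fixed explicitly, which is how
  the solver is validated against dense normal-equations ridge solutions.
* `level` (default 0.95): pointwise band level.

### Numerical choices

* Basis columns are computed on rescaled time $t/s$ (with $s$ the largest
  observed time): raw degree-5 powers of minutes are ill-conditioned.
  Because rescaling is a diagonal reparameterization (no intercept shift),
  coefficients, variances and the joint covariance are mapped back to the
  raw time scale exactly.
* The REML/ML criterion is profiled down to a one-dimensional search over
  $\log\lambda$ (interval $[-30, 30]$ on the rescaled basis) using the
  Woodbury identity, so each evaluation costs one $K \times K$ Cholesky.
  A boundary solution ($\hat\sigma_u^2 \to 0$) is a valid fit — the
  degree-$p$ polynomial — and is flagged, not rejected.
* At $t = \kappa_k$ the truncated basis value is defined as 0, the
  continuous limit.
* Duplicate time points are allowed and treated as replicate observations.
* A residual sum of squares that collapses numerically (noiseless
  polynomial input) is floored at machine level so the criterion stays
  finite; any $\lambda$ then reproduces the polynomial exactly, which the
  tests assert to $10^{-6}$.

### Confidence bands

Bands are pointwise and plug-in: conditional on $(\hat\sigma_u^2,
\hat\sigma_\epsilon^2)$, the coefficient-error covariance is
$\sigma_\epsilon^2 (C'C+\lambda D)^{-1}$ — the mixed-model covariance that
accounts for shrinkage bias on average under the random-effects
interpretation of $u$ — and the band is the normal quantile times the
mapped standard error. Smoothing-parameter uncertainty is ignored, the
standard choice in mixed-model software. Consequences measured by the
validation suite: pooled interior coverage of nominal 95% bands is about
93–94% for the canonical saturating truth ($80(1-e^{-1.5t})$, $\sigma = 1$,
$n = 400$, 200 replicates). Coverage degrades for truths that a quintic
polynomial absorbs almost entirely (REML then drives $\hat\sigma_u^2$ to
the boundary and the residual smoothing bias is comparable to the tiny SE)
and for very sharp staircase steps (penalization bias concentrates at the
steps). This is a known property of plug-in penalized-spline bands, not a
defect of the solver, and is why the coverage study uses the canonical
smooth aggregation shape.

## The multi-dose model and the nanoparticle contrast

With $D$ conditions (ordered agonist-only doses ascending, then
agonist-plus-nanoparticle doses ascending),

$$y_{dj} = f_1(t_j) + \sum_{d=2}^{D} I_d\, f_d(t_j) + \epsilon_{dj},$$

where $f_1$ is the mean curve of the reference condition (the lowest
agonist-only dose, which carries no indicator) and $f_d$ ($d \ge 2$) are
smooth deviation curves; the condition-$d$ mean is $l_d = f_1 + f_d$. All
curves share one knot set (placed from the pooled times) and — a design
choice — one smoothing variance $\sigma_u^2$, so the whole model is a
single mixed model with one $\lambda$ and one joint covariance. There is no
standard default for per-curve smoothing in such indicator models, and a
shared component keeps every between-condition contrast an exact linear map
of one coefficient vector, which makes contrast standard errors exact
linear algebra. The residual variance is likewise shared across conditions.

The nanoparticle effect at paired dose level $s$ is
$\hat h_s(t) = \hat l_{np(s)}(t) - \hat l_{ag(s)}(t)$ and the overall
effect is the arithmetic mean of the $\hat h_s$ — an identity on the
estimates, asserted at machine precision in the tests, not a refit. Because
$f_1$ cancels in every contrast, the contrasts are invariant to which
condition is the reference *up to the penalty*: the ridge penalty is
expressed in the reference parameterization, so reparameterizing perturbs
the smoothing slightly. On a low-noise fixture the tests bound this
perturbation by 0.5 percent aggregation; exact invariance holds only in the
unpenalized limit. The nano-effect display takes its baseline condition as
an argument rather than hard-coding one.

## Phase-plane reconstruction

For a fixed condition, pairing the fitted level $\hat f(t)$ with the fitted
velocity $\hat f'(t)$ at the same times gives an empirical trajectory in
the $(y, \dot y)$ plane. Two laws are fitted:

* **Linear:** $\hat f'(t) = \gamma_0 + \gamma_1 \hat f(t) + e_t$ by OLS,
  reporting $\gamma_0$ (intercept, %/min), $\gamma_1$ (slope, 1/min), naive
  SEs, residual variance $\tau^2$ and the one-predictor adjusted $R^2 = 1 -
  (1-R^2)(n-1)/(n-2)$, both raw and clipped at zero (the tabulation
  convention when comparing dose levels, where a non-informative low-dose
  fit can go slightly negative). The single steady state is
  $y^* = -\gamma_0/\gamma_1$, stable iff $\gamma_1 < 0$.
* **Smooth:** $\hat f'(t) = \gamma_0 + g(\hat f(t)) + e_t$ with $g$ a
  penalized truncated-power spline over the aggregation axis (the same
  solver; knots at quantiles of $\hat y$ with $K = \min(\lfloor n/4
  \rfloor, 20)$, degree 5). Steady states are located by a dense sign-change
  scan refined by bisection to $|F(y^*)| <$ `tolerance`, and stability by
  the sign of the numerically differentiated law; slopes smaller in
  magnitude than the tolerance are flagged indeterminate.

Default choices, all exposed as arguments:

* Phase points are taken at the observation times, not on a uniform $y$
  grid, and 5% of the time span is trimmed at each end (`trim = 0.05`)
  because spline derivative estimates are least reliable at range ends.
* The smooth-law steady-state search widens the observed aggregation range
  by 5% per side (`extend = 0.05`): a trajectory relaxing to its steady
  state approaches it from one side, so the root generically sits just
  beyond the largest fitted value. A steady state can only be located where
  the data actually approach it — the validation study therefore runs its
  logistic trajectory long enough (duration 20 min at $r = 0.8$/min) for
  the plateau to be effectively attained.
* OLS standard errors ignore the serial correlation of smoothed values and
  the estimation error in the phase points; they are reported as naive.

## What the synthetic generator emulates — and what it does not

The generator produces equally spaced traces over $[0, T]$ (default
$T = 7$ min, $L = 400$) from five families chosen to span the observed
kinetic repertoire: `saturating` (high-dose monotone rise), `rise_decay`
(biexponential rise then de-aggregation, peak at
$\log(\lambda_1/\lambda_2)/(\lambda_1-\lambda_2)$), `staircase` (logistic
steps plus an exponentially damped sinusoid — built from $C^\infty$
components because the estimators assume continuous second derivatives),
and exact solutions of the linear and logistic phase laws (closed forms
used as oracles). Dose designs add a strictly increasing dose ladder,
replicates, and an additive smooth nanoparticle offset
($a(1-e^{-rt})$, or a logistic ramp for a positive onset), mirroring the
subtractive definition of the effect contrast. Noise is additive Gaussian,
homoscedastic, independent by default; values are deliberately not clipped
to $[0, 100]$ because clipping would break the additive-noise model the
estimators assume.

Passing the recovery tests on these data shows the estimation machinery is
correct under its own assumptions. It does not show robustness to what real
aggregometer output adds: instrument drift and calibration offsets,
heteroscedastic or strongly autocorrelated noise, genuine subject-level
curve heterogeneity, and non-Gaussian artifacts (stirring events). Dose is
treated as an ordered unitless label throughout — published dose tables
mix unit conventions, and nothing in the models uses the numeric value
beyond ordering and pairing.

## Validation problem sizes

The test suite and `scripts/acceptance.R` use: 20 random small instances
($n \le 100$, $K \le 5$, $p \in \{2,3,5\}$) for the fixed-$\lambda$
ridge-oracle equivalence at $10^{-8}$ relative; 10 random fits for
derivative/finite-difference agreement at $10^{-4}$ relative; 20 replicates
($L = 400$, $\sigma = 0.5$) for linear phase-law recovery within 10% and
the fixed point within 5%; a 5-dose two-group design ($L = 200$,
$\sigma = 1$, offset amplitude 15) for nanoparticle-effect recovery within
1.5 uniformly, with 100 null replicates ($L = 60$) for the 2-SE exceedance
calibration at $\le 15\%$; and 200 replicates ($n = 400$, $\sigma = 1$) for
the band-coverage study at $\ge 85\%$. The independent oracles are dense
normal-equations ridge solves, central finite differences, closed-form ODE
solutions cross-checked against `deSolve` integration, and `nlme::lme` on
the identical mixed model.

## Known limitations

* Plug-in pointwise bands (no simultaneous bands; smoothing-parameter
  uncertainty ignored); under-coverage for polynomial-absorbable or very
  sharp truths as quantified above.
* Naive phase-law SEs (serial correlation and generated-regressor error
  ignored).
* One shared smoothing variance per model; per-condition residual variances
  are not estimated.
* No B-spline or smoothing-spline alternatives, no shape constraints, no
  mechanistic (receptor-level) simulation, and no formal hypothesis test of
  the nanoparticle effect — the contrast is an estimate with bands, not a
  test statistic.
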