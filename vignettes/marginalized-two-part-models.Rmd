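---
title: "Marginalized two-part models for clustered semicontinuous data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marginalized two-part models for clustered semicontinuous data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtpreg)
```

## The problem

Semicontinuous outcomes — case-fatality rates per 100 cases, health-care
expenditures, consumption amounts — combine a point mass at exactly zero with
a continuous, right-skewed distribution on the positive reals. The classical
two-part (hurdle) treatment models `Pr(Y > 0)` with logistic regression and
`Y | Y > 0` with a positive distribution such as the log-normal. Its
likelihood factorizes, so the two parts can be fit separately, but the
continuous-part coefficients then describe only the *conditional* mean of the
positive outcomes. A covariate can appear protective among the positives
while raising the overall burden through the zero part, and no single
coefficient answers the question practitioners usually ask: what happens to
`E(Y)`, zeros included?

The marginalized two-part (mTP) model answers that question directly. It
keeps the logistic zero part,

    logit Pr(Y_ij > 0) = z_ij' alpha + b_1i,

but places the second linear predictor on the *marginal* mean,

    log E(Y_ij) = log nu_ij = x_ij' beta + b_2i,

so that `exp(beta_k)` is the multiplicative change in the overall mean per
unit covariate change. Observations are clustered (index `i` runs over, e.g.,
WHO regions in country-level mortality data), and each part carries its own
cluster-level normal random intercept, `b_1i ~ N(0, sd_b1^2)` and
`b_2i ~ N(0, sd_b2^2)`, taken independent of one another.

## Families for the positive part

**Log-normal (LN).** If `Y | Y > 0 ~ LN(mu, sigma^2)`, the marginal moments
are

    E(Y)  = pi * exp(mu + sigma^2 / 2),
    Var(Y) = pi * exp(2 mu + sigma^2) * (exp(sigma^2) - pi).

The marginal parameterization is imposed by solving the first identity for
the location: `mu = log(nu) - log(pi) - sigma^2 / 2`
(`solve_ln_location()`). Covariates therefore enter the LN density only
through `nu`, which is what makes the likelihood non-separable: the zero-part
coefficients move `pi`, which moves `mu`.

**Beta-prime (BP).** The beta-prime (inverted-beta) distribution in its
mean-precision form has `E(Y) = mu` and `Var(Y) = mu (1 + mu) / phi`. Those
two moments force the classical shape parameters to be
`(a, b) = (mu (1 + phi), phi + 2)` (`bp_shapes()`); no other shape pair has
that mean and variance. Because `E(Y) = pi * E(Y | Y > 0)`, the conditional
BP mean under marginalization is `nu / pi` — the BP analogue of the LN
location solution. We deliberately carry all BP dispersion in `phi` alone:
an additive normal error on a BP response has no integrable place in the
two-part likelihood, so no such term is included.

A note on sign conventions: the zero part models `Pr(Y > 0)`, so a
*negative* zero-part coefficient means fewer positives, i.e. *higher* odds
of a zero outcome. Applied reports often quote the reciprocal
`1 / exp(alpha_k)` as a "k-fold reduction in the odds of a zero";
`effect_transform(coef, "zero_odds_fold")` implements exactly that
convention, and `wald_ci(..., transform = "inv_exp")` returns the matching
descending interval.

## Likelihood and integration

The marginal likelihood of cluster `i` integrates the product of
observation densities over `(b_1i, b_2i)`:

    L_i = ∫∫ Π_j [ (1 - pi_ij)^(1 - psi_ij) * (pi_ij * g(y_ij))^psi_ij ]
              φ(b1; 0, sd_b1^2) φ(b2; 0, sd_b2^2) db1 db2,

with `psi_ij = I(y_ij > 0)`. An observation is a zero iff `y == 0` exactly;
the outcomes this model targets are reported rates, and an epsilon tolerance
would silently reclassify small positive rates. The integral is evaluated on
a tensor-product Gauss–Hermite grid, by default order 15 per dimension and
*adaptive*: a damped Newton search (at most 50 iterations, gradient
tolerance 1e-8, analytic first and second derivatives of the log-integrand)
locates each cluster's joint mode, the Cholesky factor of the local inverse
curvature rescales the grid, and the summation is done in log space so that
linear predictors of several hundred in magnitude cannot overflow. Order 1
with adaptive centering is exactly the Laplace approximation. Although the
two intercepts are independent a priori, the integrand couples them
(through `mu`'s dependence on `pi`), so the adaptive transform uses the full
2 x 2 curvature, not just its diagonal. When an SD sits at the zero
boundary the corresponding dimension is not integrated at all — the
intercept is pinned at zero — and with both SDs zero the likelihood
degenerates to the plug-in evaluation.

Default orders used in this package's own studies: 15 for general use, 9
for the 30 x 50 recovery study, 5 for the replicated calibration study.
Adaptive quadrature converges very quickly in the order — on the bundled
reference data, orders 10 and 40 agree to below 1e-6 — so the lower orders
in the replicated studies are an accuracy non-issue; they were chosen as
the smallest orders at which the order-convergence check still holds.

## Estimation

`fit_mtp()` maximizes the total marginal log-likelihood jointly in
`(alpha, beta, log sigma-or-phi, log sd_b1, log sd_b2)` — the dispersion and
SDs are log-transformed for unconstrained optimization and reported on the
natural scale by the delta method. The optimizer is BFGS with central
finite-difference gradients, followed by a short full-Newton polish on the
finite-difference Hessian: quasi-Newton steps stall once the achievable
improvement in the objective drops to machine resolution, while Newton
steps continue to shrink the gradient max-norm; convergence is declared at
max-norm below `1e-6 * (1 + |loglik|)`. The polish Hessian is the observed
Fisher information, and its inverse provides the model-based covariance;
`fisher_se()` exposes the same computation for any log-likelihood. A
singular information matrix is an error that lists the flat directions,
never a silent pseudo-inverse, and non-convergence is reported as a flag
(rendered as em-dash cells in the output tables), never imputed.

Starting values come from the separable conventional fit
(`fit_conventional_tp()`): the logistic part supplies `alpha`, the
conditional continuous part supplies the dispersion and slopes, and the
continuous intercept is shifted to the marginal scale with
`log(mean(psi)) + sigma^2/2` (LN) or `log(mean(psi))` (BP) — the shift the
marginal-mean identity itself implies, rather than an ad-hoc regression on
`log(y + offset)`. Both random-intercept SDs start at 0.3, a mid-range
value on the scale of the intercepts these models produce.

The conventional baseline itself is the fixed-effects two-part model; it
exists to seed the mTP fit, to demonstrate separability, and to expose the
implied marginal mean `pi * E(Y | Y > 0)` per observation for comparison.

## The synthetic-data generator

`simulate_dataset()` draws from the exact generative process the likelihood
describes: per cluster, the two normal intercepts; per observation, a
standard-normal covariate shared by both parts (the applied data's
covariates are percentage supply shares — standardized covariates keep the
simulated conditioning comparably well behaved), then a zero with
probability `1 - pi`, otherwise an LN or BP draw with conditional mean
`nu / pi`. Cluster substreams are seeded independently from the master
seed, so enlarging one cluster cannot reshuffle another. An optional
reporting cap (e.g. 100 for per-100-case rates) truncates *after*
simulation and is off by default, mirroring the modelling choice that the
likelihood ignores the upper bound: both LN and BP have unbounded support,
exactly as fitted to bounded rate data in practice.

`make_reference_fixture()` fixes the canonical small layout — six clusters
in the image of the six WHO regions, 30 observations each, LN family,
`alpha = (0.8, 0.5)`, `beta = (1.2, 0.4)`, `sigma = 0.7`,
`sd_b1 = 0.4`, `sd_b2 = 0.3` — about one third zeros, both parts
informative.

What the generator does *not* emulate: the 23-way correlated composition of
real food-supply categories, spatial structure beyond the cluster
intercepts, or any mean-variance misspecification. Passing recovery tests
on these data therefore demonstrates the estimator is correct under the
model's own assumptions; it says nothing about robustness to model
misspecification in observational country-level data.

## Study sizes and numerical choices

- Parameter recovery: 30 clusters x 50 observations per family, quadrature
  order 9. Every parameter is checked against the truth both in absolute
  terms (bias below 0.1) and in model-SE units (within 3 SEs).
- SE calibration: 200 replicates of 15 clusters x 12 observations, order 5,
  comparing the mean model SE of the four regression coefficients with the
  empirical SD of their estimates. Variance-component SEs are not part of
  this comparison: with 15 clusters the sampling distribution of an SD
  estimate is boundary-distorted and its Wald SE is not expected to be
  calibrated.
- Quadrature validation: brute-force 2-D trapezoid integration over
  [-8 sd, 8 sd]^2 on small blocks, written directly from the densities.
- Ties and degenerate inputs: all-zero or all-positive outcomes are
  rejected with an error naming the degenerate part (a zero part with no
  zeros is not estimable); `fix_alpha` lets the zero part be pinned when a
  positive-only fit is genuinely wanted, in which case the mTP-LN fit
  reproduces ordinary log-normal regression up to the `sigma^2/2`
  intercept shift.

## A worked example

```{r example, eval = FALSE}
fix <- make_reference_fixture()
fit <- fit_mtp(fix$data, mtp_spec("LN"), mtp_control(quad_order = 9))
summary(fit)

# conventional baseline on the same data: separable by construction
cfit <- fit_conventional_tp(fix$data, mtp_spec("LN", marginalized = FALSE))
cfit$loglik - sum(cfit$loglik_parts)   # 0 up to rounding
```

## Known limitations

- Random effects are limited to one independent intercept per part; no
  correlation parameter and no higher-order terms are exposed.
- Gamma and log-skew-normal positive parts are not implemented.
- Standard errors are model-based (observed information); no bootstrap or
  sandwich variants.
- The reported significance flags are unadjusted .05-level Wald tests, one
  coefficient at a time, matching the applied reporting style this package
  reproduces; no multiplicity correction is applied.
- Fitting uses finite-difference derivatives of the quadrature-based
  likelihood; with many covariates the Hessian cost grows quadratically.
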