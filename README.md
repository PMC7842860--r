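# mtpreg — marginalized two-part regression for clustered semicontinuous data

Semicontinuous outcomes — death or recovery rates per 100 cases, health-care
costs, consumption amounts — mix an exact point mass at zero with a
right-skewed continuous distribution on the positive reals. The conventional
two-part (hurdle) model handles the mixture but its continuous-part
coefficients describe only `E(Y | Y > 0)`, the mean *among the positives*.
`mtpreg` implements the **marginalized two-part (mTP) model**, which keeps
the logistic zero part and places the second linear predictor directly on
the marginal mean, zeros included:

    logit Pr(Y_ij > 0) = z_ij' α + b_1i          (zero part)
    log  E(Y_ij)       = x_ij' β + b_2i          (marginal mean)

with independent cluster-level random intercepts `b_1i ~ N(0, σ²_b1)`,
`b_2i ~ N(0, σ²_b2)`. So `exp(β_k)` is the multiplicative effect of a
covariate on the *overall* mean — the quantity applied analyses (e.g.
country-level COVID-19 mortality grouped by WHO region) actually report.

Two positive-part families are provided:

- **log-normal (LN)** — the location is solved from the marginal-mean
  identity `μ = log ν − log π − σ²/2`;
- **beta-prime (BP)** — mean–precision parameterization with `E(Y) = μ`,
  `Var(Y) = μ(1+μ)/φ`, shape map `(a, b) = (μ(1+φ), φ+2)`, conditional mean
  `ν/π`.

The marginal likelihood integrates each cluster's contribution over
`(b_1, b_2)` with adaptive tensor-product Gauss–Hermite quadrature
(mode-recentered, Cholesky-rescaled, log-space throughout); the two parts
are maximized jointly (the mTP score does not separate) by BFGS plus a
Newton polish whose finite-difference Hessian doubles as the observed
Fisher information for model-based standard errors. A conventional
separable two-part baseline, a synthetic-data generator for the exact
generative process, CSV/JSON I/O and a small CLI round out the package.

## Worked example

```r
library(mtpreg)

fix <- make_reference_fixture()      # 6 clusters x 30 obs, LN, known truth
fit <- fit_mtp(fix$data, mtp_spec("LN"), mtp_control(quad_order = 9))
print(fit)
#> Marginalized two-part LN fit: 180 obs, 6 clusters
#> log-likelihood -386.1479; converged: TRUE
#> alpha: 0.5849 0.4393
#> beta:  1.004 0.370
#> dispersion: 0.7092   sd_b1: 0.07747   sd_b2: 0.2227
```

The generating truth was `alpha = (0.8, 0.5)`, `beta = (1.2, 0.4)`,
`sigma = 0.7`, `sd_b1 = 0.4`, `sd_b2 = 0.3`; every estimate above is within
three model-based standard errors of it. `exp(0.370) ≈ 1.45` says a one-SD
covariate increase raises the overall mean outcome by ~45%;
`effect_transform()` and the effect table in `summary(fit)` produce the
reporting conventions of the applied literature (odds ratios, "k-fold
change in the odds of a zero", percent reductions) with Wald intervals.

Command line:

```sh
Rscript inst/cli/mtp.R simulate --seed 7 --out-prefix demo
Rscript inst/cli/mtp.R fit --input demo_data.csv --outcome y --cluster region \
    --zero-covariates x1 --cont-covariates x1 --out-prefix demo
```

writes `demo_fit.json` (machine-readable, full precision) and
`demo_table.txt` (a publication-style table with per-part coefficients,
random-intercept variances, transforms, CIs and .05 significance flags).

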