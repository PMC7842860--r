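# Core distributional algebra for two-part semicontinuous models:
# links, marginal-mean identities, the beta-prime density in its
# mean-precision parameterization, and the effect transforms used in
# reporting.

#' Zero-part success probability
#'
#' Probability that the outcome is positive, `Pr(Y > 0)`, under the logistic
#' zero-part model: `logit(pi) = z'alpha + b1`, where `b1` is the
#' cluster-level random intercept of the zero part.
#'
#' @param z Numeric covariate vector for the zero part (first entry is the
#'   intercept, i.e. 1).
#' @param alpha Numeric coefficient vector, same length as `z`, on the
#'   log-odds scale.
#' @param b1 Scalar random-intercept value (0 for the population average).
#' @return Probability strictly inside (0, 1); stable for linear predictors
#'   up to about +/- 700.
#' @examples
#' logistic_prob(1, 0)            # 0.5
#' logistic_prob(c(1, 2), c(0.5, -0.25), b1 = 0.1)
#' @export
logistic_prob <- function(z, alpha, b1 = 0) {
  if (length(z) != length(alpha)) {
    stop("`z` and `alpha` must have the same length (got ",
         length(z), " and ", length(alpha), ").")
  }
  stats::plogis(sum(z * alpha) + b1)
}

#' Marginal mean under the log link
#'
#' The marginalized two-part model places covariates directly on the
#' unconditional mean: `log(nu) = x'beta + b2` with `nu = E(Y)` including
#' the zeros.
#'
#' @param x Numeric covariate vector for the continuous part (first entry 1).
#' @param beta Coefficient vector, same length as `x`, on the log scale.
#' @param b2 Scalar random-intercept value for the continuous part.
#' @return Positive marginal mean `exp(x'beta + b2)`.
#' @export
marginal_mean <- function(x, beta, b2 = 0) {
  if (length(x) != length(beta)) {
    stop("`x` and `beta` must have the same length (got ",
         length(x), " and ", length(beta), ").")
  }
  eta <- sum(x * beta) + b2
  nu <- exp(eta)
  if (!is.finite(nu)) {
    stop("marginal mean overflowed: linear predictor = ", format(eta))
  }
  nu
}

#' Marginal mean of a two-part log-normal outcome
#'
#' For a point mass at zero with `Pr(Y > 0) = pi` and `Y | Y > 0 ~ LN(mu,
#' sigma^2)`, the unconditional mean is `pi * exp(mu + sigma^2 / 2)`.
#'
#' @param pi Probability of a positive outcome, in (0, 1].
#' @param mu Log-scale location of the positive part.
#' @param sigma Log-scale standard deviation (>= 0; 0 is the degenerate
#'   point-mass limit).
#' @return The marginal mean `nu = E(Y)`.
#' @seealso [solve_ln_location()] for the inverse map.
#' @export
ln_marginal_mean <- function(pi, mu, sigma) {
  check_pi(pi, allow_zero = TRUE)
  stopifnot(sigma >= 0)
  pi * exp(mu + sigma^2 / 2)
}

#' Marginal variance of a two-part log-normal outcome
#'
#' `Var(Y) = pi * exp(2 mu + sigma^2) * (exp(sigma^2) - pi)`, which is
#' nonnegative because `exp(sigma^2) >= 1 >= pi`.
#'
#' @inheritParams ln_marginal_mean
#' @return Nonnegative marginal variance.
#' @export
ln_marginal_variance <- function(pi, mu, sigma) {
  check_pi(pi, allow_zero = TRUE)
  stopifnot(sigma >= 0)
  pi * exp(2 * mu + sigma^2) * (exp(sigma^2) - pi)
}

#' Solve the log-normal location from the marginal mean
#'
#' Inverts the marginal-mean identity `nu = pi * exp(mu + sigma^2 / 2)`:
#' `mu = log(nu) - log(pi) - sigma^2 / 2`. This is the reparameterization
#' that lets the marginalized likelihood be evaluated with a conventional
#' log-normal density while covariates act on `nu`.
#'
#' @param nu Positive marginal mean.
#' @param pi Probability of a positive outcome, in (0, 1].
#' @param sigma Log-scale standard deviation (>= 0).
#' @return The location `mu` such that [ln_marginal_mean()] returns `nu`.
#' @export
solve_ln_location <- function(nu, pi, sigma) {
  stopifnot(nu > 0, sigma >= 0)
  check_pi(pi, allow_zero = FALSE)
  log(nu) - log(pi) - sigma^2 / 2
}

check_pi <- function(pi, allow_zero) {
  lo <- if (allow_zero) pi < 0 else pi <= 0
  if (any(lo) || any(pi > 1)) {
    stop("`pi` must be a probability in ",
         if (allow_zero) "[0, 1]" else "(0, 1]", ".")
  }
  invisible(pi)
}

#' Beta-prime shape parameters from mean and precision
#'
#' Maps the mean-precision parameterization (`mu`, `phi`) with `E(Y) = mu`
#' and `Var(Y) = mu (1 + mu) / phi` to the classical beta-prime (inverted
#' beta) shapes: `shape1 = mu (1 + phi)`, `shape2 = phi + 2`. These are the
#' unique shapes with that mean and variance.
#'
#' @param mu Positive mean.
#' @param phi Positive precision.
#' @return Named numeric vector (or 2-column matrix for vector input) with
#'   entries `shape1`, `shape2`.
#' @export
bp_shapes <- function(mu, phi) {
  stopifnot(all(mu > 0), all(phi > 0))
  if (length(mu) == 1L && length(phi) == 1L) {
    return(c(shape1 = mu * (1 + phi), shape2 = phi + 2))
  }
  cbind(shape1 = mu * (1 + phi), shape2 = phi + 2)
}

#' Beta-prime density (mean-precision form)
#'
#' Density of the beta-prime distribution parameterized by its mean `mu` and
#' precision `phi`: `f(y) = y^(a-1) (1+y)^(-a-b) / B(a, b)` with
#' `(a, b) = bp_shapes(mu, phi)`. Support is the positive reals; exact zeros
#' belong to the binary part of a two-part model and are rejected.
#'
#' @param y Positive outcome value(s).
#' @param mu Positive mean.
#' @param phi Positive precision; `Var(Y) = mu (1 + mu) / phi`.
#' @param log Return the log-density?
#' @return Density (or log-density) values.
#' @export
bp_density <- function(y, mu, phi, log = FALSE) {
  if (any(y <= 0)) stop("beta-prime density requires y > 0.")
  stopifnot(all(mu > 0), all(phi > 0))
  a <- mu * (1 + phi)
  b <- phi + 2
  ld <- (a - 1) * base::log(y) - (a + b) * log1p(y) - lbeta(a, b)
  if (log) ld else exp(ld)
}

#' Random beta-prime deviates (mean-precision form)
#'
#' Draws via the gamma-ratio representation: if `G1 ~ Gamma(a, 1)` and
#' `G2 ~ Gamma(b, 1)` independently, then `G1 / G2` is beta-prime with
#' shapes `(a, b)`.
#'
#' @param n Number of draws.
#' @inheritParams bp_density
#' @return Numeric vector of positive draws with mean `mu`.
#' @export
bp_rng <- function(n, mu, phi) {
  stopifnot(all(mu > 0), all(phi > 0))
  a <- mu * (1 + phi)
  b <- phi + 2
  stats::rgamma(n, shape = a) / stats::rgamma(n, shape = b)
}

#' Reporting transforms of regression coefficients
#'
#' Turns a coefficient into the quantity quoted in results tables:
#' \describe{
#'   \item{`odds_ratio`}{`exp(coef)` — multiplicative change in the odds of
#'     a positive outcome per unit covariate increase.}
#'   \item{`zero_odds_fold`}{for negative coefficients, `1 / exp(coef)`,
#'     read as a k-fold reduction in the odds of a zero outcome; for
#'     nonnegative coefficients, `exp(coef)`.}
#'   \item{`pct_change`}{`100 * (1 - exp(coef))`, the percent reduction in
#'     the marginal mean for a negative continuous-part coefficient.}
#' }
#'
#' @param coef Finite coefficient value.
#' @param kind One of `"odds_ratio"`, `"zero_odds_fold"`, `"pct_change"`.
#' @return The transformed effect.
#' @examples
#' effect_transform(-1.417, "zero_odds_fold")  # ~ 4.1251
#' effect_transform(0.0736, "odds_ratio")      # ~ 1.076
#' effect_transform(-4.7273, "pct_change")     # ~ 99.11
#' @export
effect_transform <- function(coef,
                             kind = c("odds_ratio", "zero_odds_fold",
                                      "pct_change")) {
  kind <- match.arg(kind)
  stopifnot(is.finite(coef))
  switch(kind,
    odds_ratio = exp(coef),
    zero_odds_fold = if (coef < 0) 1 / exp(coef) else exp(coef),
    pct_change = 100 * (1 - exp(coef))
  )
}
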