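# Shared fixtures and independent oracles for the test suite.

# A small single-cluster block with zeros and positives.
toy_block <- function() {
  y <- c(0, 2.1, 0.7, 5.3, 0)
  x <- c(-0.5, 0.2, 1.1, -0.8, 0.9)
  list(y = y, x = x,
       data = mtp_data(y, rep("A", length(y)), Z = cbind(1, x)),
       params = mtp_params(alpha = c(0.4, -0.3), beta = c(0.8, 0.5),
                           dispersion = 0.9, sd_b1 = 0.6, sd_b2 = 0.4))
}

# Independent brute-force oracle: 2-D trapezoid integration of the cluster
# marginal likelihood over [-8 sd, 8 sd]^2, written directly from the model
# densities (plogis / dnorm / lbeta), not via the package's quadrature
# engine.
trapezoid_cluster_loglik <- function(y, x, params, family, ng = 501) {
  b1g <- seq(-8 * params$sd_b1, 8 * params$sd_b1, length.out = ng)
  b2g <- seq(-8 * params$sd_b2, 8 * params$sd_b2, length.out = ng)
  Z <- cbind(1, x)
  eta1 <- drop(Z %*% params$alpha)
  eta2 <- drop(Z %*% params$beta)
  pos <- which(y > 0)
  lp1 <- vapply(b1g, function(b1) {
    p <- plogis(eta1 + b1)
    sum(ifelse(y > 0, log(p), log(1 - p)))
  }, numeric(1))
  H <- matrix(0, ng, ng)
  for (i in seq_len(ng)) {
    p <- plogis(eta1[pos] + b1g[i])
    nu <- exp(outer(eta2[pos], b2g, "+"))       # npos x ng
    if (family == "LN") {
      s <- params$dispersion
      mu <- log(nu) - log(p) - s^2 / 2
      lp2 <- colSums(dnorm(log(y[pos]), mu, s, log = TRUE) - log(y[pos]))
    } else {
      phi <- params$dispersion
      a <- (nu / p) * (1 + phi)
      lp2 <- colSums((a - 1) * log(y[pos]) - (a + phi + 2) * log1p(y[pos]) -
                       lbeta(a, phi + 2))
    }
    H[i, ] <- lp1[i] + lp2 +
      dnorm(b1g[i], 0, params$sd_b1, log = TRUE) +
      dnorm(b2g, 0, params$sd_b2, log = TRUE)
  }
  w <- rep(1, ng); w[c(1, ng)] <- 0.5
  mx <- max(H)
  mx + log(drop(t(w) %*% exp(H - mx) %*% w) *
             diff(b1g)[1] * diff(b2g)[1])
}

# True parameters used across the recovery / calibration studies.
study_truth <- function(family = "LN") {
  mtp_params(alpha = c(0.5, 0.4), beta = c(1.0, 0.3),
             dispersion = if (family == "LN") 0.8 else 3,
             sd_b1 = 0.5, sd_b2 = 0.3)
}
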