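# Marginal log-likelihood of the two-part model with independent cluster
# random intercepts in the zero and continuous parts. The per-cluster double
# integral over (b1, b2) is evaluated by (adaptive) Gauss-Hermite quadrature
# on a tensor grid; everything is computed in log space.

#' Gauss-Hermite quadrature rule
#'
#' Nodes and weights for the weight function `exp(-u^2)`. With the standard
#' normal change of variables the weights sum to 1; `adaptive = TRUE`
#' recenters and rescales the grid at the mode of each cluster's integrand
#' (order 1 with `adaptive = TRUE` is the Laplace approximation).
#'
#' @param order Number of nodes per random-effect dimension (>= 1).
#' @param adaptive Recenter/rescale per cluster at the integrand mode?
#' @return An object of class `gh_rule` with fields `order`, `nodes`,
#'   `weights`, `adaptive`.
#' @export
gh_rule <- function(order = 15, adaptive = TRUE) {
  stopifnot(order >= 1)
  if (order == 1L) {
    g <- list(x = 0, w = sqrt(pi))
  } else {
    g <- pracma::gaussHermite(order)
  }
  structure(list(order = as.integer(order), nodes = g$x, weights = g$w,
                 adaptive = isTRUE(adaptive)),
            class = "gh_rule")
}

#' @export
print.gh_rule <- function(x, ...) {
  cat(sprintf("Gauss-Hermite rule: order %d per dimension%s\n", x$order,
              if (x$adaptive) ", adaptive" else ""))
  invisible(x)
}

#' Zero-part log-likelihood of one observation
#'
#' `psi * log(pi) + (1 - psi) * log(1 - pi)` with `pi` from
#' [logistic_prob()], evaluated through stable log-probabilities so that
#' extreme linear predictors do not overflow.
#'
#' @param psi 0/1 indicator of a positive outcome.
#' @inheritParams logistic_prob
#' @return Log-likelihood contribution (finite for finite inputs).
#' @export
obs_loglik_zero <- function(psi, z, alpha, b1 = 0) {
  stopifnot(psi %in% c(0, 1))
  if (length(z) != length(alpha)) stop("`z`/`alpha` length mismatch.")
  eta <- sum(z * alpha) + b1
  if (psi == 1) stats::plogis(eta, log.p = TRUE) else stats::plogis(-eta, log.p = TRUE)
}

#' Continuous-part log-likelihood of one positive observation
#'
#' Under the marginalized parameterization covariates enter only through the
#' marginal mean `nu = exp(x'beta + b2)`. For the log-normal family the
#' density is evaluated at location `solve_ln_location(nu, pi, sigma)`; for
#' beta-prime the conditional mean is `nu / pi` (since
#' `E(Y) = pi * E(Y | Y > 0)`).
#'
#' @param y Positive outcome value.
#' @param x Continuous-part covariate vector.
#' @param params An [mtp_params()] object.
#' @param pi Zero-part probability `Pr(Y > 0)` for this observation.
#' @param b2 Continuous-part random-intercept value.
#' @param family `"LN"` or `"BP"`.
#' @return Log-density of `y` under the positive part.
#' @export
obs_loglik_positive <- function(y, x, params, pi, b2 = 0,
                                family = c("LN", "BP")) {
  family <- match.arg(family)
  if (y <= 0) stop("`y` must be positive; zeros belong to the binary part.")
  check_pi(pi, allow_zero = FALSE)
  nu <- marginal_mean(x, params$beta, b2)
  if (family == "LN") {
    mu <- solve_ln_location(nu, pi, params$dispersion)
    stats::dnorm(log(y), mu, params$dispersion, log = TRUE) - log(y)
  } else {
    bp_density(y, nu / pi, params$dispersion, log = TRUE)
  }
}

# ---- vectorized engine ----------------------------------------------------

# Precompute everything that does not depend on the random effects.
make_ctx <- function(data, params, spec) {
  check_dims(data, params)
  j <- as.integer(data$cluster)
  pos <- which(data$psi == 1L)
  list(j = j, m = nlevels(data$cluster), psi = data$psi,
       eta1_0 = drop(data$Z %*% params$alpha),
       eta2_0 = drop(data$X %*% params$beta),
       pos = pos, jp = j[pos],
       logy = log(data$y[pos]), log1py = log1p(data$y[pos]),
       disp = params$dispersion, family = spec$family,
       marginalized = spec$marginalized,
       levels = levels(data$cluster))
}

# Per-cluster summed log-likelihood at a batch of random-effect values.
# B1, B2 are m x K matrices (one column per quadrature point; K = 1 gives
# plain vectors); the whole batch is evaluated in one matrix sweep and
# aggregated with a single rowsum. Returns an m x K matrix.
cluster_eval_ll <- function(ctx, B1, B2) {
  if (is.null(dim(B1))) B1 <- matrix(B1, ncol = 1L)
  if (is.null(dim(B2))) B2 <- matrix(B2, ncol = 1L)
  j <- ctx$j
  E1 <- ctx$eta1_0 + B1[j, , drop = FALSE]          # n x K
  LOGPI <- stats::plogis(E1, log.p = TRUE)
  LL <- LOGPI - E1                                  # log(1 - pi) rows
  p <- ctx$pos
  if (length(p)) {
    LL[p, ] <- LOGPI[p, , drop = FALSE]
    E2 <- ctx$eta2_0[p] + B2[ctx$jp, , drop = FALSE]
    if (ctx$family == "LN") {
      sig <- ctx$disp
      MU <- if (ctx$marginalized) {
        E2 - LOGPI[p, , drop = FALSE] - sig^2 / 2
      } else E2
      LL[p, ] <- LL[p, , drop = FALSE] - 0.5 * log(2 * pi) - log(sig) -
        (ctx$logy - MU)^2 / (2 * sig^2) - ctx$logy
    } else {
      phi <- ctx$disp
      LOGM <- if (ctx$marginalized) E2 - LOGPI[p, , drop = FALSE] else E2
      A <- exp(LOGM) * (1 + phi)
      b0 <- phi + 2
      LL[p, ] <- LL[p, , drop = FALSE] + (A - 1) * ctx$logy -
        (A + b0) * ctx$log1py - lbeta(A, b0)
    }
  }
  rowsum(LL, j)
}

# Vector version with gradient and Hessian with respect to (b1, b2), used by
# the per-cluster Newton mode search. Derivatives follow from
# d mu / d b1 = -(1 - pi) under the marginalized parameterization (mu
# depends on b1 through log pi).
cluster_eval_deriv <- function(ctx, b1, b2) {
  j <- ctx$j
  eta1 <- ctx$eta1_0 + b1[j]
  logpi <- stats::plogis(eta1, log.p = TRUE)
  ll <- logpi - eta1
  ll[ctx$pos] <- logpi[ctx$pos]
  n <- length(eta1)
  pr <- exp(logpi)
  g1 <- ctx$psi - pr
  h11 <- -pr * (1 - pr)
  g2 <- numeric(n); h22 <- numeric(n); h12 <- numeric(n)
  if (length(ctx$pos)) {
    p <- ctx$pos
    eta2p <- ctx$eta2_0[p] + b2[ctx$jp]
    logpip <- logpi[p]
    if (ctx$family == "LN") {
      sig <- ctx$disp
      mu <- if (ctx$marginalized) eta2p - logpip - sig^2 / 2 else eta2p
      r <- (ctx$logy - mu) / sig^2
      ll[p] <- ll[p] - 0.5 * log(2 * pi) - log(sig) -
        0.5 * sig^2 * r^2 - ctx$logy
      q1 <- if (ctx$marginalized) 1 - exp(logpip) else 0
      g2[p] <- r
      g1[p] <- g1[p] - r * q1
      h22[p] <- -1 / sig^2
      h12[p] <- q1 / sig^2
      h11[p] <- h11[p] - q1^2 / sig^2 + r * exp(logpip) * q1
    } else {
      phi <- ctx$disp
      logm <- if (ctx$marginalized) eta2p - logpip else eta2p
      a <- exp(logm) * (1 + phi)
      b0 <- phi + 2
      ll[p] <- ll[p] + (a - 1) * ctx$logy - (a + b0) * ctx$log1py -
        lbeta(a, b0)
      ga <- ctx$logy - ctx$log1py - digamma(a) + digamma(a + b0)
      s <- a * ga
      tt <- s + a^2 * (trigamma(a + b0) - trigamma(a))
      q1 <- if (ctx$marginalized) 1 - exp(logpip) else 0
      g2[p] <- s
      g1[p] <- g1[p] - s * q1
      h22[p] <- tt
      h12[p] <- -q1 * tt
      h11[p] <- h11[p] + q1^2 * tt + exp(logpip) * q1 * s
    }
  }
  agg <- rowsum(cbind(ll, g1, g2, h11, h12, h22), j)
  list(ll = agg[, 1L], g = agg[, 2:3, drop = FALSE],
       h = agg[, 4:6, drop = FALSE])
}

# Joint log-integrand (observations + active priors) per cluster; matrix in,
# matrix out.
log_integrand <- function(ctx, B1, B2, sd1, sd2) {
  H <- cluster_eval_ll(ctx, B1, B2)
  # priors only for the integrated (active) dimensions; an SD at the zero
  # boundary means that intercept is fixed at 0, not integrated
  if (sd1 > 1e-8) H <- H + stats::dnorm(B1, 0, sd1, log = TRUE)
  if (sd2 > 1e-8) H <- H + stats::dnorm(B2, 0, sd2, log = TRUE)
  H
}

# Damped Newton search for the per-cluster joint mode of the integrand over
# the active random-effect dimensions. `active` is a logical pair; inactive
# dimensions stay fixed at zero. Vectorized across clusters.
newton_modes <- function(ctx, sd1, sd2, active, start = NULL,
                         max_iter = 50, tol = 1e-8) {
  m <- ctx$m
  b <- if (is.null(start)) matrix(0, m, 2) else start
  b[, !active] <- 0
  hcur <- drop(log_integrand(ctx, b[, 1], b[, 2], sd1, sd2))
  g1 <- g2 <- h11 <- h12 <- h22 <- rep(0, m)
  for (it in seq_len(max_iter)) {
    ev <- cluster_eval_deriv(ctx, b[, 1], b[, 2])
    if (active[1]) { g1 <- ev$g[, 1] - b[, 1] / sd1^2; h11 <- ev$h[, 1] - 1 / sd1^2 }
    if (active[2]) { g2 <- ev$g[, 2] - b[, 2] / sd2^2; h22 <- ev$h[, 3] - 1 / sd2^2 }
    h12 <- if (all(active)) ev$h[, 2] else rep(0, m)
    gmax <- max(c(if (active[1]) abs(g1), if (active[2]) abs(g2)))
    if (gmax < tol) break
    if (all(active)) {
      dt <- h11 * h22 - h12^2
      ok <- is.finite(dt) & dt > 0 & h11 < 0
      s1 <- ifelse(ok, -(h22 * g1 - h12 * g2) / dt, g1 / (1 + abs(g1)))
      s2 <- ifelse(ok, -(h11 * g2 - h12 * g1) / dt, g2 / (1 + abs(g2)))
    } else if (active[1]) {
      s1 <- ifelse(is.finite(h11) & h11 < 0, -g1 / h11, g1 / (1 + abs(g1)))
      s2 <- rep(0, m)
    } else {
      s2 <- ifelse(is.finite(h22) & h22 < 0, -g2 / h22, g2 / (1 + abs(g2)))
      s1 <- rep(0, m)
    }
    lam <- rep(1, m)
    bt <- b; ht <- hcur
    for (half in 1:30) {
      bt <- cbind(b[, 1] + lam * s1, b[, 2] + lam * s2)
      ht <- drop(log_integrand(ctx, bt[, 1], bt[, 2], sd1, sd2))
      bad <- !(ht >= hcur - 1e-10)
      if (!any(bad)) break
      lam[bad] <- lam[bad] / 2
    }
    keep <- ht >= hcur          # reject clusters that never improved
    b[keep, ] <- bt[keep, ]
    hcur[keep] <- ht[keep]
  }
  ev <- cluster_eval_deriv(ctx, b[, 1], b[, 2])
  if (active[1]) { h11 <- ev$h[, 1] - 1 / sd1^2 }
  if (active[2]) { h22 <- ev$h[, 3] - 1 / sd2^2 }
  h12 <- if (all(active)) ev$h[, 2] else rep(0, m)
  list(b = b, h11 = h11, h12 = h12, h22 = h22)
}

row_logsumexp <- function(H) {
  mx <- H[cbind(seq_len(nrow(H)), max.col(H, ties.method = "first"))]
  mx + log(rowSums(exp(H - mx)))
}

# Per-cluster marginal log-likelihood contributions (length-m vector).
marginal_ll_clusters <- function(data, params, spec, quad,
                                 start_modes = NULL) {
  ctx <- make_ctx(data, params, spec)
  m <- ctx$m
  sd1 <- params$sd_b1; sd2 <- params$sd_b2
  active <- c(sd1 > 1e-8, sd2 > 1e-8)
  if (!any(active)) {
    ll <- drop(cluster_eval_ll(ctx, numeric(m), numeric(m)))
    return(list(ll = ll, modes = matrix(0, m, 2), levels = ctx$levels))
  }
  nodes <- quad$nodes; lw <- log(quad$weights); K <- quad$order
  s2 <- sqrt(2)
  # centers and scale factors of the quadrature grid per cluster
  if (quad$adaptive) {
    ns <- newton_modes(ctx, sd1, sd2, active, start = start_modes)
    Bc <- ns$b
    if (all(active)) {
      dt <- ns$h11 * ns$h22 - ns$h12^2
      ok <- is.finite(dt) & dt > 0 & ns$h11 < 0
      S11 <- ifelse(ok, -ns$h22 / dt, sd1^2)
      S12 <- ifelse(ok, ns$h12 / dt, 0)
      S22 <- ifelse(ok, -ns$h11 / dt, sd2^2)
      C11 <- sqrt(S11); C21 <- S12 / C11; C22 <- sqrt(pmax(S22 - C21^2, 1e-12))
      ldetC <- log(C11) + log(C22)
    } else if (active[1]) {
      C11 <- ifelse(is.finite(ns$h11) & ns$h11 < 0, sqrt(-1 / ns$h11), sd1)
      ldetC <- log(C11)
    } else {
      C22 <- ifelse(is.finite(ns$h22) & ns$h22 < 0, sqrt(-1 / ns$h22), sd2)
      ldetC <- log(C22)
    }
  } else {
    Bc <- matrix(0, m, 2)
    if (all(active)) {
      C11 <- rep(sd1, m); C21 <- rep(0, m); C22 <- rep(sd2, m)
      ldetC <- log(C11) + log(C22)
    } else if (active[1]) {
      C11 <- rep(sd1, m); ldetC <- log(C11)
    } else {
      C22 <- rep(sd2, m); ldetC <- log(C22)
    }
  }
  if (all(active)) {
    gj <- rep(seq_len(K), each = K)      # tensor grid indices
    gk <- rep(seq_len(K), times = K)
    B1 <- Bc[, 1] + s2 * C11 %o% nodes[gj]
    B2 <- Bc[, 2] + s2 * (C21 %o% nodes[gj] + C22 %o% nodes[gk])
    H <- log_integrand(ctx, B1, B2, sd1, sd2)
    H <- H + rep(lw[gj] + lw[gk] + nodes[gj]^2 + nodes[gk]^2,
                 each = m)
    ll <- log(2) + ldetC + row_logsumexp(H)
  } else {
    if (active[1]) {
      B1 <- Bc[, 1] + s2 * C11 %o% nodes
      B2 <- matrix(0, m, K)
    } else {
      B2 <- Bc[, 2] + s2 * C22 %o% nodes
      B1 <- matrix(0, m, K)
    }
    H <- log_integrand(ctx, B1, B2, sd1, sd2)
    H <- H + rep(lw + nodes^2, each = m)
    ll <- 0.5 * log(2) + ldetC + row_logsumexp(H)
  }
  list(ll = ll, modes = if (quad$adaptive) Bc else matrix(0, m, 2),
       levels = ctx$levels)
}

#' Marginal log-likelihood of one cluster
#'
#' Integrates the product of observation likelihoods over the cluster's two
#' independent random intercepts, `b1 ~ N(0, sd_b1^2)` and
#' `b2 ~ N(0, sd_b2^2)`, on a tensor-product Gauss-Hermite grid (adaptively
#' recentered at the joint mode of the integrand when `quad$adaptive`).
#' When both SDs are zero the integral degenerates to the plug-in
#' log-likelihood at `b1 = b2 = 0`.
#'
#' @param block An [mtp_data()] containing exactly one cluster.
#' @param params An [mtp_params()] object.
#' @param spec An [mtp_spec()] object.
#' @param quad A [gh_rule()].
#' @return Scalar log marginal likelihood contribution of the cluster.
#' @export
cluster_marginal_loglik <- function(block, params, spec, quad = gh_rule()) {
  stopifnot(inherits(block, "mtp_data"))
  if (nlevels(block$cluster) != 1L) {
    stop("`block` must contain a single cluster; got ",
         nlevels(block$cluster), ".")
  }
  marginal_ll_clusters(block, params, spec, quad)$ll[[1L]]
}

#' Total marginal log-likelihood
#'
#' Sum of [cluster_marginal_loglik()] over all clusters in the dataset.
#'
#' @param data An [mtp_data()] object (nonempty).
#' @inheritParams cluster_marginal_loglik
#' @return Scalar log-likelihood.
#' @export
total_loglik <- function(data, params, spec, quad = gh_rule()) {
  stopifnot(inherits(data, "mtp_data"))
  if (length(data$y) == 0L) stop("empty dataset.")
  res <- marginal_ll_clusters(data, params, spec, quad)
  bad <- !is.finite(res$ll)
  if (any(bad)) {
    stop("nonfinite likelihood contribution for cluster(s): ",
         paste(res$levels[bad], collapse = ", "))
  }
  sum(res$ll)
}
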