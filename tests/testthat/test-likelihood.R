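test_that("Gauss-Hermite weights normalize to one and the rule degenerates to Laplace", {
  for (ord in c(1, 5, 15, 40)) {
    q <- gh_rule(ord)
    expect_lt(abs(sum(q$weights) / sqrt(pi) - 1), 1e-12)
  }
  # order 1, adaptive: single node at the mode = Laplace approximation
  tb <- toy_block()
  lap <- cluster_marginal_loglik(tb$data, tb$params, mtp_spec("LN"),
                                 gh_rule(1, adaptive = TRUE))
  ref <- cluster_marginal_loglik(tb$data, tb$params, mtp_spec("LN"),
                                 gh_rule(25, adaptive = TRUE))
  expect_lt(abs(lap - ref), 0.1)   # Laplace is close but not exact
})

test_that("zero-part observation log-likelihood matches hand arithmetic", {
  expect_equal(obs_loglik_zero(1, 1, 0), log(0.5))
  expect_equal(obs_loglik_zero(0, 1, -30), 0, tolerance = 1e-12)
  # a 2-observation block at pi = 0.3
  a <- log(0.3 / 0.7)
  expect_equal(obs_loglik_zero(1, 1, a) + obs_loglik_zero(0, 1, a),
               log(0.3) + log(0.7), tolerance = 1e-12)
  # no overflow far into the tails
  expect_true(is.finite(obs_loglik_zero(0, 1, 700)))
})

test_that("positive-part log-likelihood enforces the marginal parameterization", {
  p <- mtp_params(alpha = 0, beta = 0, dispersion = 1)
  # nu = pi * exp(sigma^2/2) makes mu = 0: LN log-density at its median
  pi0 <- 0.5
  p$beta <- log(pi0 * exp(0.5))
  expect_equal(obs_loglik_positive(1, 1, p, pi0, 0, "LN"),
               -log(sqrt(2 * pi)), tolerance = 1e-12)
  # BP with pi = 1 reduces to the plain beta-prime density
  pb <- mtp_params(alpha = 0, beta = log(2.5), dispersion = 4)
  expect_equal(obs_loglik_positive(1.3, 1, pb, 1, 0, "BP"),
               bp_density(1.3, 2.5, 4, log = TRUE))
  expect_error(obs_loglik_positive(0, 1, p, 0.5, 0, "LN"), "positive")
})

test_that("degenerate random effects reduce to the plug-in likelihood", {
  tb <- toy_block()
  p0 <- mtp_params(tb$params$alpha, tb$params$beta, tb$params$dispersion, 0, 0)
  for (fam in c("LN", "BP")) {
    plug <- sum(vapply(seq_along(tb$y), function(o) {
      z <- c(1, tb$x[o])
      pi_o <- logistic_prob(z, p0$alpha)
      v <- obs_loglik_zero(as.integer(tb$y[o] > 0), z, p0$alpha)
      if (tb$y[o] > 0) {
        v <- v + obs_loglik_positive(tb$y[o], z, p0, pi_o, 0, fam)
      }
      v
    }, numeric(1)))
    expect_equal(cluster_marginal_loglik(tb$data, p0, mtp_spec(fam),
                                         gh_rule(15)), plug,
                 tolerance = 1e-12)
  }
})

test_that("adaptive and high-order non-adaptive quadrature agree", {
  tb <- toy_block()
  idx <- 1:3
  block3 <- mtp_data(tb$y[idx], rep("A", 3), Z = cbind(1, tb$x[idx]))
  for (fam in c("LN", "BP")) {
    ad <- cluster_marginal_loglik(block3, tb$params, mtp_spec(fam),
                                  gh_rule(10, adaptive = TRUE))
    na <- cluster_marginal_loglik(block3, tb$params, mtp_spec(fam),
                                  gh_rule(30, adaptive = FALSE))
    expect_lt(abs(ad - na), 1e-6)
  }
})

test_that("quadrature agrees with brute-force trapezoid integration", {
  tb <- toy_block()
  for (fam in c("LN", "BP")) {
    ours <- cluster_marginal_loglik(tb$data, tb$params, mtp_spec(fam),
                                    gh_rule(15))
    brute <- trapezoid_cluster_loglik(tb$y, tb$x, tb$params, fam)
    expect_lt(abs(ours - brute) / abs(brute), 1e-6)
  }
})

test_that("increasing the quadrature order leaves the likelihood unchanged", {
  fix <- make_reference_fixture()
  l10 <- total_loglik(fix$data, fix$truth, mtp_spec("LN"), gh_rule(10))
  l40 <- total_loglik(fix$data, fix$truth, mtp_spec("LN"), gh_rule(40))
  expect_lt(abs(l10 - l40), 1e-6)
})

test_that("total log-likelihood is additive over clusters", {
  fix <- make_reference_fixture()
  d <- fix$data; p <- fix$truth
  spec <- mtp_spec("LN"); q <- gh_rule(9)
  per_cluster <- vapply(levels(d$cluster), function(cl) {
    idx <- which(d$cluster == cl)
    block <- mtp_data(d$y[idx], d$cluster[idx], d$Z[idx, ], d$X[idx, ])
    cluster_marginal_loglik(block, p, spec, q)
  }, numeric(1))
  expect_equal(total_loglik(d, p, spec, q), sum(per_cluster),
               tolerance = 1e-12)
  # duplicating every cluster under new labels doubles the log-likelihood
  d2 <- mtp_data(c(d$y, d$y),
                 c(as.character(d$cluster), paste0(d$cluster, "_dup")),
                 rbind(d$Z, d$Z), rbind(d$X, d$X))
  expect_equal(total_loglik(d2, p, spec, q),
               2 * total_loglik(d, p, spec, q), tolerance = 1e-10)
})

test_that("permuting observations and relabeling clusters leave the likelihood invariant", {
  fix <- make_reference_fixture()
  d <- fix$data; p <- fix$truth
  spec <- mtp_spec("LN"); q <- gh_rule(9)
  base <- total_loglik(d, p, spec, q)
  set.seed(5)
  perm <- sample(length(d$y))
  dp <- mtp_data(d$y[perm], d$cluster[perm], d$Z[perm, ], d$X[perm, ])
  expect_equal(total_loglik(dp, p, spec, q), base, tolerance = 1e-10)
  dr <- d
  levels(dr$cluster) <- paste0("region_", seq_len(nlevels(d$cluster)))
  expect_identical(total_loglik(dr, p, spec, q), base)
})

test_that("log-space evaluation survives extreme linear predictors on large blocks", {
  set.seed(8)
  n <- 1000
  x <- rnorm(n)
  y <- ifelse(runif(n) < 0.5, rlnorm(n, 1, 0.5), 0)
  d <- mtp_data(y, rep("A", n), Z = cbind(1, x))
  p <- mtp_params(alpha = c(200, -50), beta = c(2, 0.5), dispersion = 1,
                  sd_b1 = 0.5, sd_b2 = 0.5)
  ll <- cluster_marginal_loglik(d, p, mtp_spec("LN"), gh_rule(9))
  expect_true(is.finite(ll))
})

test_that("empty data and dimension mismatches raise informative errors", {
  fix <- make_reference_fixture()
  bad <- mtp_params(alpha = c(0, 0, 0), beta = c(1, 0), dispersion = 1)
  expect_error(total_loglik(fix$data, bad, mtp_spec("LN")), "alpha")
  tb <- toy_block()
  two <- mtp_data(c(0, 1), c("A", "B"), Z = cbind(c(1, 1)))
  expect_error(cluster_marginal_loglik(two, mtp_params(0, 0, 1),
                                       mtp_spec("LN")), "single cluster")
})
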