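test_that("conventional two-part likelihood separates into its two components", {
  fix <- make_reference_fixture()
  d <- fix$data
  fit <- fit_conventional_tp(d, mtp_spec("LN", marginalized = FALSE))
  # independent oracle: glm for the binary part, dlnorm at the lm solution
  df <- data.frame(psi = d$psi, x = d$Z[, 2])
  gl <- glm(psi ~ x, binomial, data = df)
  pos <- d$psi == 1
  lmfit <- lm(log(d$y[pos]) ~ d$X[pos, 2])
  sig <- sqrt(mean(residuals(lmfit)^2))
  ll_cont <- sum(dlnorm(d$y[pos], fitted(lmfit), sig, log = TRUE))
  expect_lt(abs(fit$loglik - (as.numeric(logLik(gl)) + ll_cont)), 1e-8)
  expect_equal(unname(fit$params$alpha), unname(coef(gl)), tolerance = 1e-8)
  # the separable total equals the engine's plug-in evaluation too
  engine <- total_loglik(d, fit$params, mtp_spec("LN", marginalized = FALSE),
                         gh_rule(9))
  expect_lt(abs(engine - fit$loglik), 1e-8)
})

test_that("conventional fits are deterministic and expose the implied marginal mean", {
  fix <- make_reference_fixture()
  f1 <- fit_conventional_tp(fix$data, mtp_spec("LN", marginalized = FALSE))
  f2 <- fit_conventional_tp(fix$data, mtp_spec("LN", marginalized = FALSE))
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$loglik, f2$loglik)
  # Monte-Carlo check of E(Y) = pi * exp(mu + sigma^2/2) under the fitted model
  set.seed(31)
  p <- f1$params
  nrep <- 400
  sims <- replicate(nrep, {
    pi_hat <- plogis(drop(fix$data$Z %*% p$alpha))
    mu <- drop(fix$data$X %*% p$beta)
    mean(ifelse(runif(length(pi_hat)) < pi_hat,
                rlnorm(length(mu), mu, p$dispersion), 0))
  })
  expect_lt(abs(mean(sims) - mean(f1$fitted_marginal_mean)),
            3 * sd(sims) / sqrt(nrep))
})

test_that("observed-information SEs match the closed-form logistic information", {
  set.seed(14)
  n <- 400
  x <- rnorm(n)
  eta <- 0.3 + 0.8 * x
  ypsi <- rbinom(n, 1, plogis(eta))
  gl <- glm(ypsi ~ x, binomial)
  Z <- cbind(1, x)
  ll <- function(th) {
    lp <- drop(Z %*% th)
    sum(ypsi * plogis(lp, log.p = TRUE) + (1 - ypsi) * plogis(-lp, log.p = TRUE))
  }
  fe <- fisher_se(ll, coef(gl))
  expect_equal(fe$se, unname(sqrt(diag(vcov(gl)))), tolerance = 1e-4)
  # a flat direction is detected, not silently inverted
  Z2 <- cbind(Z, x)   # duplicated covariate
  ll2 <- function(th) {
    lp <- drop(Z2 %*% th)
    sum(ypsi * plogis(lp, log.p = TRUE) + (1 - ypsi) * plogis(-lp, log.p = TRUE))
  }
  expect_error(fisher_se(ll2, c(coef(gl), 0)), "singular")
})

test_that("duplicating clusters four-fold halves the standard errors", {
  fix <- make_reference_fixture()
  d <- fix$data
  f1 <- fit_conventional_tp(d, mtp_spec("LN", marginalized = FALSE))
  y4 <- rep(d$y, 4)
  cl4 <- paste0(rep(as.character(d$cluster), 4), "_", rep(1:4, each = length(d$y)))
  Z4 <- d$Z[rep(seq_along(d$y), 4), ]
  f4 <- fit_conventional_tp(mtp_data(y4, cl4, Z4),
                            mtp_spec("LN", marginalized = FALSE))
  ratio <- f1$se[1:4] / f4$se[1:4]
  expect_true(all(abs(ratio - 2) < 0.02))
})

test_that("Wald intervals transform endpoint-wise, reversing under reciprocal", {
  expect_equal(wald_ci(0, 1, 0.95, "none"),
               c(-1, 1) * qnorm(0.975), tolerance = 1e-12)
  # reciprocal-odds reporting: descending endpoints around 1/exp(estimate)
  se <- 0.544
  ci <- wald_ci(-1.417, se, 0.95, "inv_exp")
  expect_equal(ci, exp(1.417 + c(1, -1) * qnorm(0.975) * se), tolerance = 1e-12)
  expect_gt(ci[1], ci[2])
  ci2 <- wald_ci(0.0736, 0.03, 0.95, "exp")
  expect_true(ci2[1] < exp(0.0736) && exp(0.0736) < ci2[2])
  expect_error(wald_ci(0, -1), "nonnegative")
})

test_that("with no zeros and pi forced to one the fit is ordinary log-normal regression", {
  set.seed(17)
  n <- 300
  x <- rnorm(n)
  y <- rlnorm(n, 0.5 + 0.4 * x, 0.6)
  d <- mtp_data(y, rep(c("A", "B"), length.out = n), Z = cbind(1, x))
  fit <- fit_mtp(d, mtp_spec("LN"),
                 mtp_control(quad_order = 5, include_ranef = FALSE,
                             fix_alpha = c(35, 0)))
  ols <- lm(log(y) ~ x)
  sig2 <- fit$params$dispersion^2
  # marginal-scale intercept = conditional intercept + sigma^2/2 when pi = 1
  expect_equal(unname(fit$params$beta[1]), unname(coef(ols)[1]) + sig2 / 2,
               tolerance = 1e-4)
  expect_equal(unname(fit$params$beta[2]), unname(coef(ols)[2]),
               tolerance = 1e-4)
  expect_equal(fit$params$dispersion, sqrt(mean(residuals(ols)^2)),
               tolerance = 1e-4)
})

test_that("degenerate outcomes raise errors naming the degenerate part", {
  x <- rnorm(20)
  all_zero <- mtp_data(rep(0, 20), rep("A", 20), Z = cbind(1, x))
  expect_error(fit_mtp(all_zero), "continuous part")
  all_pos <- mtp_data(rlnorm(20), rep("A", 20), Z = cbind(1, x))
  expect_error(fit_mtp(all_pos), "zero part")
})

test_that("the marginalized fit targets the overall mean, the conventional fit the positives", {
  set.seed(23)
  truth <- study_truth("LN")
  truth$sd_b1 <- 0; truth$sd_b2 <- 0
  d <- simulate_dataset(mtp_design(4, 800, truth, family = "LN", seed = 99))
  mfit <- fit_mtp(d, mtp_spec("LN"),
                  mtp_control(quad_order = 5, include_ranef = FALSE))
  cfit <- fit_conventional_tp(d, mtp_spec("LN", marginalized = FALSE))
  # cell comparison at covariate quartile bins
  qs <- quantile(d$X[, 2], c(0.25, 0.75))
  for (x0 in qs) {
    sel <- abs(d$X[, 2] - x0) < 0.15
    nu_hat <- exp(mfit$params$beta[1] + mfit$params$beta[2] * x0)
    cell_mean <- mean(d$y[sel])
    se_cell <- sd(d$y[sel]) / sqrt(sum(sel))
    expect_lt(abs(nu_hat - cell_mean), 4 * se_cell)
    # the conventional coefficients track the positives instead
    cond_hat <- exp(cfit$params$beta[1] + cfit$params$beta[2] * x0 +
                      cfit$params$dispersion^2 / 2)
    pos_mean <- mean(d$y[sel & d$psi == 1])
    expect_gt(cond_hat, nu_hat)   # conditional mean exceeds marginal mean
    se_pos <- sd(d$y[sel & d$psi == 1]) / sqrt(sum(sel & d$psi == 1))
    expect_lt(abs(cond_hat - pos_mean), 4 * se_pos)
  }
})

test_that("random-effect SDs shrink to the boundary when the truth has none", {
  truth <- study_truth("LN")
  truth$sd_b1 <- 0; truth$sd_b2 <- 0
  d <- simulate_dataset(mtp_design(30, 100, truth, family = "LN", seed = 303))
  fit <- fit_mtp(d, mtp_spec("LN"), mtp_control(quad_order = 5))
  expect_lte(fit$params$sd_b1, 0.05)
  expect_lte(fit$params$sd_b2, 0.05)
})

test_that("the optimum is stable under perturbed restarts", {
  truth <- study_truth("LN")
  d <- simulate_dataset(mtp_design(15, 12, truth, family = "LN", seed = 55))
  base <- fit_mtp(d, mtp_spec("LN"), mtp_control(quad_order = 5))
  set.seed(56)
  for (r in 1:3) {
    start <- mtp_params(truth$alpha + rnorm(2, 0, 0.3),
                        truth$beta + rnorm(2, 0, 0.3),
                        truth$dispersion * exp(rnorm(1, 0, 0.2)),
                        sd_b1 = 0.2, sd_b2 = 0.4)
    refit <- fit_mtp(d, mtp_spec("LN"),
                     mtp_control(quad_order = 5, start = start))
    expect_lt(abs(refit$loglik - base$loglik), 1e-4)
  }
})
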