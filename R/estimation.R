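# Maximum-likelihood fitting: marginalized two-part models (joint,
# non-separable score) and the conventional two-part baseline (separable,
# fit part by part), with observed-information standard errors.

#' Fitting control parameters
#'
#' @param quad_order Gauss-Hermite order per random-effect dimension.
#' @param adaptive Use adaptive (mode-recentered) quadrature?
#' @param grad_tol Convergence: gradient max-norm below
#'   `grad_tol * (1 + |loglik|)`.
#' @param par_tol Relative parameter-change tolerance passed to the
#'   optimizer.
#' @param max_iter Maximum quasi-Newton iterations.
#' @param include_ranef Estimate the two random-intercept SDs? If `FALSE`
#'   they are fixed at zero (no clustering).
#' @param fix_alpha Optional fixed zero-part coefficient vector; when given,
#'   the zero part is held at these values instead of being estimated (used
#'   e.g. to force `pi` to 1 on data without zeros).
#' @param start Optional [mtp_params()] starting values.
#' @param verbose Print optimizer progress?
#' @return List of control settings.
#' @export
mtp_control <- function(quad_order = 15, adaptive = TRUE, grad_tol = 1e-6,
                        par_tol = 1e-8, max_iter = 500,
                        include_ranef = TRUE, fix_alpha = NULL,
                        start = NULL, verbose = FALSE) {
  list(quad_order = quad_order, adaptive = adaptive, grad_tol = grad_tol,
       par_tol = par_tol, max_iter = max_iter,
       include_ranef = isTRUE(include_ranef), fix_alpha = fix_alpha,
       start = start, verbose = isTRUE(verbose))
}

# ---- numeric differentiation ----------------------------------------------

num_grad <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(i) {
    h <- eps * max(1, abs(x[i]))
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

num_hessian <- function(f, x, eps = 1e-4) {
  k <- length(x)
  h <- eps * pmax(1, abs(x))
  H <- matrix(NA_real_, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) {
    ei <- replace(numeric(k), i, h[i])
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    if (i > 1) {
      for (j in seq_len(i - 1)) {
        ej <- replace(numeric(k), j, h[j])
        H[i, j] <- H[j, i] <-
          (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
          (4 * h[i] * h[j])
      }
    }
  }
  H
}

#' Observed-information variance matrix and standard errors
#'
#' Inverts the negative Hessian of a log-likelihood at its maximum (the
#' observed Fisher information), with the Hessian obtained by central finite
#' differences.
#'
#' @param loglik Function of the parameter vector returning the
#'   log-likelihood.
#' @param theta_hat Parameter vector at an interior maximum.
#' @return List with `vcov` (inverse information) and `se`
#'   (`sqrt(diag(vcov))`).
#' @export
fisher_se <- function(loglik, theta_hat) {
  info <- num_hessian(function(th) -loglik(th), theta_hat)
  invert_information(info)
}

invert_information <- function(info) {
  info <- (info + t(info)) / 2
  ev <- eigen(info, symmetric = TRUE)
  null_dir <- ev$values < max(abs(ev$values)) * 1e-10
  if (any(null_dir)) {
    dirs <- apply(ev$vectors[, null_dir, drop = FALSE], 2, function(v) {
      paste(sprintf("%.3f", v), collapse = ", ")
    })
    stop("singular Fisher information; null direction(s): ",
         paste(dirs, collapse = " | "))
  }
  vc <- ev$vectors %*% diag(1 / ev$values, length(ev$values)) %*% t(ev$vectors)
  list(vcov = vc, se = sqrt(pmax(diag(vc), 0)))
}

#' Wald confidence interval with optional endpoint transform
#'
#' Computes `estimate +/- z * se` and transforms the endpoints: `"exp"` for
#' odds/mean ratios, `"inv_exp"` for the reciprocal-odds reporting of
#' zero-part effects (endpoints are returned in descending order, the
#' convention for k-fold-reduction intervals).
#'
#' @param estimate Coefficient estimate.
#' @param se Nonnegative standard error.
#' @param level Confidence level in (0, 1).
#' @param transform One of `"none"`, `"exp"`, `"inv_exp"`.
#' @return Numeric vector `c(low, high)` on the transformed scale.
#' @export
wald_ci <- function(estimate, se, level = 0.95,
                    transform = c("none", "exp", "inv_exp")) {
  transform <- match.arg(transform)
  if (se < 0) stop("`se` must be nonnegative.")
  stopifnot(level > 0, level < 1)
  z <- stats::qnorm((1 + level) / 2)
  ci <- c(estimate - z * se, estimate + z * se)
  switch(transform,
    none = ci,
    exp = exp(ci),
    inv_exp = exp(-ci)   # reciprocal reverses the order: (high, low)
  )
}

# ---- internal parameterization ---------------------------------------------
# theta = (free alpha, beta, log dispersion, [log sd_b1, log sd_b2])

theta_skeleton <- function(data, control) {
  list(q1 = ncol(data$Z), p1 = ncol(data$X),
       est_alpha = is.null(control$fix_alpha),
       est_ranef = control$include_ranef,
       fix_alpha = control$fix_alpha)
}

theta_pack <- function(params, sk) {
  th <- c(if (sk$est_alpha) params$alpha, params$beta, log(params$dispersion))
  if (sk$est_ranef) {
    th <- c(th, log(max(params$sd_b1, 1e-4)), log(max(params$sd_b2, 1e-4)))
  }
  th
}

theta_unpack <- function(theta, sk) {
  i <- 0L
  if (sk$est_alpha) {
    alpha <- theta[seq_len(sk$q1)]; i <- sk$q1
  } else {
    alpha <- sk$fix_alpha
  }
  beta <- theta[i + seq_len(sk$p1)]
  i <- i + sk$p1
  disp <- exp(theta[i + 1L]); i <- i + 1L
  if (sk$est_ranef) {
    sd1 <- exp(theta[i + 1L]); sd2 <- exp(theta[i + 2L])
  } else {
    sd1 <- sd2 <- 0
  }
  mtp_params(alpha, beta, disp, sd1, sd2)
}

theta_names <- function(data, sk) {
  nm <- c(if (sk$est_alpha) paste0("zero_", colnames(data$Z)),
          paste0("mean_", colnames(data$X)), "log_dispersion")
  if (sk$est_ranef) nm <- c(nm, "log_sd_b1", "log_sd_b2")
  nm
}

# objective closure with warm-started cluster modes across calls
make_objective <- function(data, spec, quad, sk) {
  cache <- new.env(parent = emptyenv())
  cache$modes <- NULL
  fn <- function(theta) {
    params <- theta_unpack(theta, sk)
    # extreme trial values can underflow lgamma correction terms; those
    # evaluations are simply poor candidates, not failures worth surfacing
    res <- tryCatch(
      suppressWarnings(marginal_ll_clusters(data, params, spec, quad,
                                            start_modes = cache$modes)),
      error = function(e) NULL)
    if (is.null(res) || any(!is.finite(res$ll))) return(1e10)
    cache$modes <- res$modes
    -sum(res$ll)
  }
  fn
}

# ---- conventional two-part fit ---------------------------------------------

#' Conventional (separable) two-part fit
#'
#' Fits the logistic zero part and the conditional continuous part as two
#' separate maximizations — possible because the conventional two-part
#' likelihood factorizes, unlike the marginalized model's. Continuous-part
#' coefficients act on the conditional location of `Y | Y > 0` (log scale).
#' Random intercepts are not estimated here; the fit is the fixed-effects
#' baseline and supplies starting values for [fit_mtp()].
#'
#' @param data An [mtp_data()] with both zero and positive outcomes.
#' @param spec An [mtp_spec()] with `marginalized = FALSE`.
#' @param control A [mtp_control()] list.
#' @return An object of class `mtp_fit`; `$fitted_marginal_mean` holds the
#'   implied per-observation marginal mean `pi * E(Y | Y > 0)`.
#' @export
fit_conventional_tp <- function(data, spec = mtp_spec(marginalized = FALSE),
                                control = mtp_control()) {
  stopifnot(inherits(data, "mtp_data"))
  if (spec$marginalized) stop("`spec$marginalized` must be FALSE here.")
  check_degenerate(data)
  psi <- data$psi
  zfit <- stats::glm.fit(data$Z, psi, family = stats::binomial())
  alpha <- zfit$coefficients
  p1 <- ncol(data$Z)
  va <- tryCatch(chol2inv(zfit$qr$qr[seq_len(p1), seq_len(p1), drop = FALSE]),
                 error = function(e) matrix(NA_real_, p1, p1))
  pi_hat <- stats::plogis(drop(data$Z %*% alpha))
  ll_zero <- sum(psi * log(pi_hat) + (1 - psi) * log1p(-pi_hat))

  pos <- psi == 1L
  yp <- data$y[pos]
  Xp <- data$X[pos, , drop = FALSE]
  if (spec$family == "LN") {
    lf <- stats::lm.fit(Xp, log(yp))
    beta <- lf$coefficients
    sigma <- sqrt(sum(lf$residuals^2) / length(yp))
    disp <- sigma
    ll_cont <- sum(stats::dlnorm(yp, drop(Xp %*% beta), sigma, log = TRUE))
    XtX_inv <- chol2inv(qr.R(lf$qr))
    vb <- sigma^2 * XtX_inv
    se_disp <- sigma / sqrt(2 * length(yp))
    cond_mean <- exp(drop(data$X %*% beta) + sigma^2 / 2)
    cont_conv <- TRUE
  } else {
    nll <- function(th) {
      b <- th[-length(th)]; phi <- exp(th[length(th)])
      mu <- exp(drop(Xp %*% b))
      -sum(suppressWarnings(bp_density(yp, mu, phi, log = TRUE)))
    }
    lf0 <- stats::lm.fit(Xp, log(yp))
    m0 <- exp(drop(Xp %*% lf0$coefficients))
    v0 <- max(mean((yp - m0)^2), 1e-6)
    phi0 <- min(max(mean(m0 * (1 + m0)) / v0, 0.1), 1e4)
    th0 <- c(lf0$coefficients, log(phi0))
    opt <- stats::optim(th0, nll, method = "BFGS",
                        control = list(maxit = control$max_iter))
    beta <- opt$par[-length(opt$par)]
    disp <- exp(opt$par[length(opt$par)])
    ll_cont <- -opt$value
    Hc <- num_hessian(nll, opt$par)
    vc_all <- tryCatch(solve(Hc), error = function(e) {
      matrix(NA_real_, length(opt$par), length(opt$par))
    })
    vb <- vc_all[seq_along(beta), seq_along(beta), drop = FALSE]
    se_disp <- disp * sqrt(vc_all[length(opt$par), length(opt$par)])
    cond_mean <- exp(drop(data$X %*% beta))
    cont_conv <- opt$convergence == 0
  }
  names(beta) <- colnames(data$X)
  names(alpha) <- colnames(data$Z)
  params <- mtp_params(alpha, beta, disp, 0, 0)
  se <- c(sqrt(pmax(diag(va), 0)), sqrt(pmax(diag(vb), 0)), se_disp)
  vcov_nat <- as.matrix(Matrix_bdiag(list(va, vb, se_disp^2)))
  nm <- c(paste0("zero_", colnames(data$Z)),
          paste0("mean_", colnames(data$X)), "dispersion")
  dimnames(vcov_nat) <- list(nm, nm)
  names(se) <- nm
  out <- new_mtp_fit(params, se, vcov_nat, ll_zero + ll_cont,
                     converged = zfit$converged && cont_conv,
                     data = data, spec = spec, control = control)
  out$loglik_parts <- c(zero = ll_zero, continuous = ll_cont)
  out$fitted_marginal_mean <- pi_hat * cond_mean
  out
}

# small block-diagonal helper (avoids a Matrix dependency)
Matrix_bdiag <- function(blocks) {
  blocks <- lapply(blocks, as.matrix)
  sizes <- vapply(blocks, nrow, integer(1))
  out <- matrix(0, sum(sizes), sum(sizes))
  at <- 0L
  for (b in blocks) {
    idx <- at + seq_len(nrow(b))
    out[idx, idx] <- b
    at <- at + nrow(b)
  }
  out
}

check_degenerate <- function(data) {
  if (all(data$psi == 0L)) {
    stop("all outcomes are zero: the continuous part is degenerate.")
  }
  if (all(data$psi == 1L)) {
    stop("no zero outcomes: the zero part is degenerate ",
         "(use `mtp_control(fix_alpha = )` to force pi).")
  }
  invisible(TRUE)
}

# ---- marginalized two-part fit ---------------------------------------------

#' Fit a marginalized two-part model
#'
#' Jointly maximizes the marginal likelihood over zero-part and
#' continuous-part coefficients, the dispersion, and the two
#' random-intercept SDs, using quasi-Newton (BFGS) optimization with
#' adaptive Gauss-Hermite quadrature over the cluster random effects. The
#' two parts cannot be fit separately: the score couples them through the
#' marginal-mean reparameterization. Starting values come from the
#' conventional separable fit, with the continuous-part intercept shifted to
#' the marginal scale (`+ log(mean(psi)) + sigma^2/2` for log-normal,
#' `+ log(mean(psi))` for beta-prime).
#'
#' @param data An [mtp_data()] with both zero and positive outcomes.
#' @param spec An [mtp_spec()] with `marginalized = TRUE`.
#' @param control A [mtp_control()] list.
#' @return An object of class `mtp_fit` with estimates, observed-information
#'   SEs, covariance, log-likelihood, convergence diagnostics and an effect
#'   table; non-convergence is reported via `converged = FALSE`, never
#'   silently imputed.
#' @export
fit_mtp <- function(data, spec = mtp_spec(), control = mtp_control()) {
  stopifnot(inherits(data, "mtp_data"))
  if (!spec$marginalized) stop("`spec$marginalized` must be TRUE; use fit_conventional_tp() otherwise.")
  if (is.null(control$fix_alpha)) check_degenerate(data)
  quad <- gh_rule(control$quad_order, control$adaptive)
  sk <- theta_skeleton(data, control)

  start <- control$start
  if (is.null(start)) {
    if (is.null(control$fix_alpha)) {
      base <- fit_conventional_tp(data, mtp_spec(spec$family, marginalized = FALSE),
                                  control = mtp_control(max_iter = control$max_iter))
      alpha0 <- base$params$alpha
      beta0 <- base$params$beta
      disp0 <- base$params$dispersion
      pibar <- mean(data$psi)
      beta0[1] <- beta0[1] + log(pibar) +
        if (spec$family == "LN") disp0^2 / 2 else 0
    } else {
      alpha0 <- control$fix_alpha
      lf <- stats::lm.fit(data$X[data$psi == 1L, , drop = FALSE],
                          log(data$y[data$psi == 1L]))
      beta0 <- lf$coefficients
      disp0 <- if (spec$family == "LN") {
        max(sqrt(mean(lf$residuals^2)), 1e-3)
      } else 1
      beta0[1] <- beta0[1] + if (spec$family == "LN") disp0^2 / 2 else 0
    }
    start <- mtp_params(alpha0, beta0, disp0,
                        sd_b1 = 0.3, sd_b2 = 0.3)
  }
  th0 <- theta_pack(start, sk)
  fn <- make_objective(data, spec, quad, sk)
  gr <- function(th) num_grad(fn, th)
  opt <- stats::optim(th0, fn, gr, method = "BFGS",
                      control = list(maxit = control$max_iter,
                                     reltol = control$par_tol,
                                     trace = if (control$verbose) 1 else 0))
  # Newton polish: the quasi-Newton phase stalls once function-value changes
  # drop below machine resolution; full Newton steps on the numerically
  # differentiated Hessian drive the gradient max-norm down further, and the
  # final Hessian doubles as the observed information.
  th <- opt$par
  fval <- opt$value
  g <- gr(th)
  H <- NULL
  for (polish in 1:5) {
    if (max(abs(g)) <= control$grad_tol * (1 + abs(fval))) break
    H <- num_hessian(fn, th)
    step <- tryCatch(-solve(H, g), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    lam <- 1
    improved <- FALSE
    while (lam >= 1 / 64) {
      f1 <- fn(th + lam * step)
      if (is.finite(f1) && f1 <= fval + 1e-12) { improved <- TRUE; break }
      lam <- lam / 2
    }
    if (!improved) break
    th <- th + lam * step
    fval <- f1
    g <- gr(th)
  }
  if (is.null(H)) H <- num_hessian(fn, th)
  gnorm <- max(abs(g))
  loglik <- -fval
  converged <- opt$convergence == 0 &&
    gnorm <= control$grad_tol * (1 + abs(loglik))
  params <- theta_unpack(th, sk)
  names(params$alpha) <- colnames(data$Z)
  names(params$beta) <- colnames(data$X)

  # observed information on the internal (unconstrained) scale, then the
  # delta method back to the natural scale for dispersion and the SDs
  nm_int <- theta_names(data, sk)
  fe <- tryCatch(invert_information(H),
                 error = function(e) {
                   warning("Fisher information not invertible: ",
                           conditionMessage(e))
                   k <- length(th)
                   list(vcov = matrix(NA_real_, k, k), se = rep(NA_real_, k))
                 })
  jac <- rep(1, length(th))
  ntrans <- 1L + if (sk$est_ranef) 2L else 0L
  tail_idx <- length(th) - ntrans + seq_len(ntrans)
  jac[tail_idx] <- exp(th[tail_idx])
  vcov_nat <- fe$vcov * tcrossprod(jac)
  nm_nat <- sub("^log_", "", nm_int)
  dimnames(vcov_nat) <- list(nm_nat, nm_nat)
  se <- sqrt(pmax(diag(vcov_nat), 0))

  out <- new_mtp_fit(params, se, vcov_nat, loglik, converged,
                     data = data, spec = spec, control = control)
  out$vcov_internal <- fe$vcov
  out$theta_internal <- stats::setNames(th, nm_int)
  out$grad_norm <- gnorm
  out$optim_counts <- opt$counts
  out
}

new_mtp_fit <- function(params, se, vcov, loglik, converged, data, spec,
                        control, ci_level = 0.95) {
  out <- list(params = params, se = se, vcov = vcov, loglik = loglik,
              converged = converged,
              n_obs = length(data$y), n_clusters = nlevels(data$cluster),
              spec = spec, control = control, ci_level = ci_level)
  out$effect_table <- effect_table(out)
  class(out) <- "mtp_fit"
  out
}

# Reporting table: per-coefficient transforms, Wald CIs and .05-level flags.
# Zero-part coefficients are on the log-odds of a POSITIVE outcome; the
# zero-odds fold transform reports the reciprocal, the field's "k-fold
# change in the odds of a zero" convention.
effect_table <- function(fit) {
  p <- fit$params
  if (is.null(names(p$alpha))) {
    names(p$alpha) <- c("(Intercept)",
                        if (length(p$alpha) > 1L)
                          paste0("z", seq_len(length(p$alpha) - 1L)))
  }
  if (is.null(names(p$beta))) {
    names(p$beta) <- c("(Intercept)",
                       if (length(p$beta) > 1L)
                         paste0("x", seq_len(length(p$beta) - 1L)))
  }
  nm_z <- paste0("zero_", names(p$alpha))
  nm_x <- paste0("mean_", names(p$beta))
  est <- c(p$alpha, p$beta)
  se <- fit$se[c(nm_z, nm_x)]
  z <- est / se
  pval <- 2 * stats::pnorm(-abs(z))
  lvl <- fit$ci_level
  rows <- lapply(seq_along(est), function(i) {
    zero_part <- i <= length(p$alpha)
    kind <- if (zero_part) "zero_odds_fold" else {
      if (est[i] < 0) "pct_change" else "mean_ratio"
    }
    val <- if (fit$converged) {
      if (kind == "mean_ratio") exp(est[i]) else
        effect_transform(est[i], if (kind == "pct_change") "pct_change" else "zero_odds_fold")
    } else NA_real_
    ci <- if (fit$converged && is.finite(se[i])) {
      if (zero_part && est[i] < 0) {
        wald_ci(est[i], se[i], lvl, "inv_exp")
      } else if (kind == "pct_change") {
        100 * (1 - exp(wald_ci(est[i], se[i], lvl, "none")[2:1]))
      } else {
        wald_ci(est[i], se[i], lvl, "exp")
      }
    } else c(NA_real_, NA_real_)
    data.frame(part = if (zero_part) "zero" else "mean",
               term = sub("^(zero|mean)_", "", names(est)[i]),
               estimate = unname(est[i]), se = unname(se[i]),
               p_value = unname(pval[i]), transform = kind,
               value = val, ci_1 = ci[1], ci_2 = ci[2],
               signif = is.finite(pval[i]) && pval[i] < 0.05)
  })
  do.call(rbind, rows)
}

#' @export
print.mtp_fit <- function(x, ...) {
  cat(sprintf("%s two-part %s fit: %d obs, %d clusters\n",
              if (x$spec$marginalized) "Marginalized" else "Conventional",
              x$spec$family, x$n_obs, x$n_clusters))
  cat(sprintf("log-likelihood %.4f; converged: %s\n", x$loglik,
              x$converged))
  print(x$params)
  invisible(x)
}

#' @export
summary.mtp_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.mtp_fit")
}

#' @export
print.summary.mtp_fit <- function(x, ...) {
  fit <- x$fit
  print(fit)
  tab <- fit$effect_table
  tab$sig <- ifelse(tab$signif, "*", "")
  print(format(tab, digits = 4), row.names = FALSE)
  cat(sprintf("dispersion %.4f (SE %.4f); sd_b1 %.4f; sd_b2 %.4f\n",
              fit$params$dispersion, fit$se["dispersion"],
              fit$params$sd_b1, fit$params$sd_b2))
  invisible(x)
}

#' @export
coef.mtp_fit <- function(object, ...) {
  c(stats::setNames(object$params$alpha,
                    paste0("zero_", names(object$params$alpha))),
    stats::setNames(object$params$beta,
                    paste0("mean_", names(object$params$beta))))
}

#' @export
vcov.mtp_fit <- function(object, ...) object$vcov

#' @export
logLik.mtp_fit <- function(object, ...) {
  structure(object$loglik, df = nrow(object$vcov), class = "logLik")
}
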