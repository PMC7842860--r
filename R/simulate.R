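# Synthetic clustered semicontinuous data from the exact generative
# processes the models assume: a logistic zero part and a log-normal or
# beta-prime positive part, each with its own independent cluster-level
# normal random intercept, covariates acting on the marginal mean.

#' Simulation design
#'
#' @param n_clusters Number of clusters (e.g. regions).
#' @param cluster_sizes Common cluster size, or an integer vector of length
#'   `n_clusters`.
#' @param params True [mtp_params()] generating the data.
#' @param family `"LN"` or `"BP"`.
#' @param n_covariates Number of standard-normal covariates drawn per
#'   observation and shared by both parts (in addition to the intercept).
#'   Must equal `length(alpha) - 1 == length(beta) - 1`.
#' @param seed Integer seed; the same design always yields byte-identical
#'   data. Per-cluster substreams are derived from it, so changing one
#'   cluster's size does not reshuffle the others.
#' @param cap Optional reporting cap (e.g. 100 for per-100-case rates),
#'   applied as a truncation after simulation; `NULL` (default) means no cap
#'   — the likelihood itself never uses a bound.
#' @return An object of class `mtp_design`.
#' @export
mtp_design <- function(n_clusters, cluster_sizes, params,
                       family = c("LN", "BP"), n_covariates = 1L,
                       seed = 1L, cap = NULL) {
  family <- match.arg(family)
  if (length(cluster_sizes) == 1L) {
    cluster_sizes <- rep(as.integer(cluster_sizes), n_clusters)
  }
  stopifnot(length(cluster_sizes) == n_clusters, all(cluster_sizes >= 1),
            inherits(params, "mtp_params"),
            length(params$alpha) == n_covariates + 1L,
            length(params$beta) == n_covariates + 1L)
  structure(list(n_clusters = as.integer(n_clusters),
                 cluster_sizes = cluster_sizes, params = params,
                 family = family, n_covariates = as.integer(n_covariates),
                 seed = as.integer(seed), cap = cap),
            class = "mtp_design")
}

#' Simulate a clustered semicontinuous dataset
#'
#' For each cluster draws `b1 ~ N(0, sd_b1^2)` and `b2 ~ N(0, sd_b2^2)`
#' independently; per observation draws covariates, computes
#' `pi = plogis(z'alpha + b1)` and `nu = exp(x'beta + b2)`, emits `y = 0`
#' with probability `1 - pi`, and otherwise draws from the positive part
#' with conditional mean `nu / pi`: log-normal with location
#' [solve_ln_location()] and scale `sigma`, or beta-prime with mean `nu/pi`
#' and precision `phi`. The true random intercepts are recorded in the
#' `"ranef"` attribute for diagnostics.
#'
#' @param design An [mtp_design()] object.
#' @return An [mtp_data()] with attributes `"ranef"` (data frame of true
#'   `b1`, `b2` per cluster) and `"design"`.
#' @export
simulate_dataset <- function(design) {
  stopifnot(inherits(design, "mtp_design"))
  p <- design$params
  set.seed(design$seed)
  sub <- sample.int(2147483646L, design$n_clusters)
  ys <- vector("list", design$n_clusters)
  cl <- vector("list", design$n_clusters)
  Xs <- vector("list", design$n_clusters)
  b1s <- numeric(design$n_clusters)
  b2s <- numeric(design$n_clusters)
  labels <- sprintf("C%02d", seq_len(design$n_clusters))
  for (i in seq_len(design$n_clusters)) {
    set.seed(sub[i])
    ni <- design$cluster_sizes[i]
    b1 <- stats::rnorm(1, 0, p$sd_b1)
    b2 <- stats::rnorm(1, 0, p$sd_b2)
    W <- cbind(1, matrix(stats::rnorm(ni * design$n_covariates),
                         ni, design$n_covariates))
    colnames(W) <- c("(Intercept)",
                     if (design$n_covariates > 0)
                       paste0("x", seq_len(design$n_covariates)))
    pi_i <- stats::plogis(drop(W %*% p$alpha) + b1)
    nu_i <- exp(drop(W %*% p$beta) + b2)
    psi <- stats::runif(ni) < pi_i
    y <- numeric(ni)
    if (any(psi)) {
      if (design$family == "LN") {
        mu <- log(nu_i[psi]) - log(pi_i[psi]) - p$dispersion^2 / 2
        y[psi] <- stats::rlnorm(sum(psi), mu, p$dispersion)
      } else {
        y[psi] <- bp_rng(sum(psi), nu_i[psi] / pi_i[psi], p$dispersion)
      }
    }
    if (!is.null(design$cap)) y <- pmin(y, design$cap)
    ys[[i]] <- y; Xs[[i]] <- W
    cl[[i]] <- rep(labels[i], ni)
    b1s[i] <- b1; b2s[i] <- b2
  }
  W <- do.call(rbind, Xs)
  out <- mtp_data(unlist(ys), unlist(cl), Z = W, X = W)
  attr(out, "ranef") <- data.frame(cluster = labels, b1 = b1s, b2 = b2s)
  attr(out, "design") <- design
  out
}

#' Canonical small reference fixture
#'
#' A fixed log-normal dataset of 6 clusters (mimicking the six WHO regions)
#' with 30 observations each, generated from known parameters, used
#' throughout the test suite and examples.
#'
#' @return A list with elements `data` (the 180-row [mtp_data()]) and
#'   `truth` (the generating [mtp_params()]).
#' @export
make_reference_fixture <- function() {
  truth <- mtp_params(alpha = c(0.8, 0.5), beta = c(1.2, 0.4),
                      dispersion = 0.7, sd_b1 = 0.4, sd_b2 = 0.3)
  design <- mtp_design(n_clusters = 6, cluster_sizes = 30, params = truth,
                       family = "LN", seed = 20210126 %% 2^31)
  data <- simulate_dataset(design)
  levels(data$cluster) <- c("AFR", "AMR", "EMR", "EUR", "SEAR", "WPR")
  list(data = data, truth = truth)
}
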