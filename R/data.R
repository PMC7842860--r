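# Containers: dataset, model specification, parameter set.

#' Construct a clustered semicontinuous dataset
#'
#' Bundles a nonnegative outcome, a cluster label, and the per-part design
#' matrices into the container every fitting and likelihood function
#' consumes. An observation is classified as a zero iff `y == 0` exactly;
#' no epsilon tolerance is applied, so small positive rates are never
#' silently reclassified.
#'
#' @param y Nonnegative numeric outcome (e.g. deaths per 100 cases).
#' @param cluster Cluster labels (coerced to factor), e.g. WHO region.
#' @param Z Design matrix of the zero (binary) part, first column the
#'   intercept. A vector is treated as a single column.
#' @param X Design matrix of the continuous part, first column the intercept.
#'   Defaults to `Z`: the two parts may share covariates or use entirely
#'   different ones.
#' @return An object of class `mtp_data`: a list with elements `y`, `psi`
#'   (the positivity indicator `I(y > 0)`), `cluster`, `Z`, `X`.
#' @export
mtp_data <- function(y, cluster, Z, X = Z) {
  y <- as.numeric(y)
  if (anyNA(y)) stop("`y` contains missing values; drop or impute first.")
  if (any(y < 0)) {
    stop("negative outcome at row(s) ",
         paste(utils::head(which(y < 0), 5L), collapse = ", "),
         "; semicontinuous outcomes must be >= 0.")
  }
  Z <- as_design(Z, length(y), "Z")
  X <- as_design(X, length(y), "X")
  cluster <- factor(cluster)
  if (length(cluster) != length(y)) {
    stop("`cluster` must have one label per observation.")
  }
  if (anyNA(cluster)) stop("`cluster` contains missing labels.")
  out <- list(y = y, psi = as.integer(y > 0), cluster = cluster,
              Z = Z, X = X)
  class(out) <- "mtp_data"
  out
}

as_design <- function(M, n, name) {
  if (is.null(dim(M))) M <- matrix(M, ncol = 1L, dimnames = list(NULL, name))
  M <- as.matrix(M)
  storage.mode(M) <- "double"
  if (nrow(M) != n) stop("`", name, "` must have one row per observation.")
  if (anyNA(M)) stop("`", name, "` contains missing values.")
  if (is.null(colnames(M))) {
    colnames(M) <- c("(Intercept)", paste0(tolower(name), seq_len(ncol(M) - 1L)))[seq_len(ncol(M))]
  }
  M
}

#' @export
print.mtp_data <- function(x, ...) {
  cat("Clustered semicontinuous dataset\n")
  cat(sprintf("  %d observations in %d clusters; %.1f%% zeros\n",
              length(x$y), nlevels(x$cluster), 100 * mean(x$psi == 0)))
  cat("  zero-part covariates:", paste(colnames(x$Z), collapse = ", "), "\n")
  cat("  continuous-part covariates:", paste(colnames(x$X), collapse = ", "), "\n")
  invisible(x)
}

#' Model specification
#'
#' @param family Continuous-part family: `"LN"` (log-normal) or `"BP"`
#'   (beta-prime, mean-precision parameterization).
#' @param marginalized If `TRUE` (the default) covariates act on the marginal
#'   mean `E(Y)`; if `FALSE` the conventional two-part model is used, where
#'   continuous-part covariates act on the conditional location of `Y | Y > 0`.
#' @param zero_covariates,cont_covariates Optional covariate names (taken
#'   from the data when omitted).
#' @param cluster_column Name of the cluster column (bookkeeping for I/O).
#' @return An object of class `mtp_spec`.
#' @export
mtp_spec <- function(family = c("LN", "BP"), marginalized = TRUE,
                     zero_covariates = NULL, cont_covariates = NULL,
                     cluster_column = "cluster") {
  family <- match.arg(family)
  out <- list(family = family, marginalized = isTRUE(marginalized),
              zero_covariates = zero_covariates,
              cont_covariates = cont_covariates,
              cluster_column = cluster_column)
  class(out) <- "mtp_spec"
  out
}

#' @export
print.mtp_spec <- function(x, ...) {
  cat(sprintf("%s two-part model, %s continuous part\n",
              if (x$marginalized) "Marginalized" else "Conventional",
              if (x$family == "LN") "log-normal" else "beta-prime"))
  invisible(x)
}

#' Parameter set on the natural scale
#'
#' @param alpha Zero-part coefficients (log-odds of a positive outcome).
#' @param beta Continuous-part coefficients (log marginal mean for the
#'   marginalized model; log conditional location otherwise).
#' @param dispersion Positive dispersion: `sigma` (log-scale SD) for the
#'   log-normal family, precision `phi` for beta-prime.
#' @param sd_b1,sd_b2 Nonnegative SDs of the independent cluster random
#'   intercepts in the zero and continuous parts.
#' @return An object of class `mtp_params`.
#' @export
mtp_params <- function(alpha, beta, dispersion, sd_b1 = 0, sd_b2 = 0) {
  stopifnot(is.numeric(alpha), is.numeric(beta),
            length(dispersion) == 1L, dispersion > 0,
            length(sd_b1) == 1L, sd_b1 >= 0,
            length(sd_b2) == 1L, sd_b2 >= 0)
  out <- list(alpha = stats::setNames(as.numeric(alpha), names(alpha)),
              beta = stats::setNames(as.numeric(beta), names(beta)),
              dispersion = as.numeric(dispersion),
              sd_b1 = as.numeric(sd_b1), sd_b2 = as.numeric(sd_b2))
  class(out) <- "mtp_params"
  out
}

#' @export
print.mtp_params <- function(x, ...) {
  cat("alpha:", paste(format(x$alpha, digits = 4), collapse = " "), "\n")
  cat("beta: ", paste(format(x$beta, digits = 4), collapse = " "), "\n")
  cat(sprintf("dispersion: %.4g   sd_b1: %.4g   sd_b2: %.4g\n",
              x$dispersion, x$sd_b1, x$sd_b2))
  invisible(x)
}

check_dims <- function(data, params) {
  if (ncol(data$Z) != length(params$alpha)) {
    stop("length(alpha) = ", length(params$alpha),
         " does not match ncol(Z) = ", ncol(data$Z), ".")
  }
  if (ncol(data$X) != length(params$beta)) {
    stop("length(beta) = ", length(params$beta),
         " does not match ncol(X) = ", ncol(data$X), ".")
  }
  invisible(TRUE)
}
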