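#' Configuration of a Monte-Carlo simulation cell
#'
#' Describes one data-generating condition of the simulation study: `n`
#' records on `p` predictors drawn from a zero-mean multivariate normal
#' with exchangeable correlation `rho` (optionally rescaled by a diagonal
#' `D`), and a beta-distributed response whose logit mean follows the
#' linear predictor `beta_true` with precision `phi_true`.
#'
#' @param n sample size per replicate.
#' @param rho exchangeable predictor correlation in [0, 1).
#' @param p number of predictors (default 4).
#' @param D positive diagonal scaling vector of length `p`; the predictor
#'   covariance is `diag(sqrt(D)) R diag(sqrt(D))`.
#' @param beta_true coefficients on the logit scale, length `p + 1`
#'   including the intercept (default intercept 3, slopes 0.5).
#' @param phi_true beta precision, > 0 (default 15).
#' @param reps replications (default 1000).
#' @param ridge_k ridge constant used by the shrinkage fits (default 0).
#' @param seed master integer seed.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n, rho, p = 4, D = rep(1, p),
                              beta_true = c(3, rep(0.5, p)),
                              phi_true = 15, reps = 1000, ridge_k = 0,
                              seed = 1) {
  stopifnot(n >= p + 2, length(D) == p, all(D > 0),
            length(beta_true) == p + 1, phi_true > 0, reps >= 1,
            ridge_k >= 0)
  R <- gen_correlation_matrix(p, rho)
  Sigma <- diag(sqrt(D), p) %*% R %*% diag(sqrt(D), p)
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("predictor covariance is not positive definite")
  structure(list(n = n, p = p, rho = rho, D = D, Sigma = Sigma,
                 beta_true = beta_true, phi_true = phi_true, reps = reps,
                 ridge_k = ridge_k, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Exchangeable correlation matrix
#'
#' Unit diagonal, constant off-diagonal `rho`; eigenvalues are
#' `1 + (p-1) rho` (once) and `1 - rho` (p-1 times), so the matrix is
#' positive definite for every `rho` in [0, 1).
#'
#' @param p dimension.
#' @param rho common correlation, `0 <= rho < 1`.
#' @return A `p x p` correlation matrix.
#' @export
gen_correlation_matrix <- function(p, rho) {
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  R <- matrix(rho, p, p)
  diag(R) <- 1
  R
}

#' Draw multivariate-normal predictors for a simulation cell
#'
#' @param config a [simulation_config()].
#' @return `n x p` matrix drawn from N(0, Sigma), columns named
#'   `x1 ... xp`; reproducible from `config$seed`.
#' @export
gen_mc_predictors <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  X <- MASS::mvrnorm(config$n, mu = rep(0, config$p), Sigma = config$Sigma)
  colnames(X) <- paste0("x", seq_len(config$p))
  X
}

#' Draw a beta-distributed response along a logit-linear mean
#'
#' For each row, the mean is `mu_i = plogis(beta0 + x_i' beta)` and the
#' response is drawn from the mean/precision beta law with shapes
#' `(mu_i phi, (1 - mu_i) phi)`, so `E(y) = mu` and
#' `var(y) = mu(1 - mu)/(1 + phi)`. Draws whose distance from 0 or 1
#' underflows double precision are clamped to `[1e-12, 1 - 1e-12]` so the
#' support stays strictly inside the unit interval.
#'
#' @param X predictor matrix without intercept column.
#' @param beta_true coefficients including intercept, length `ncol(X) + 1`.
#' @param phi_true precision, > 0.
#' @param seed integer seed.
#' @return Numeric vector in (0, 1) of length `nrow(X)`.
#' @export
gen_beta_response <- function(X, beta_true, phi_true, seed) {
  stopifnot(length(beta_true) == ncol(X) + 1, phi_true > 0)
  eta <- beta_true[1L] + drop(as.matrix(X) %*% beta_true[-1L])
  mu <- stats::plogis(eta)
  if (any(mu <= 0) || any(mu >= 1)) stop("mean left (0, 1)")  # defensive
  set.seed(seed)
  y <- stats::rbeta(nrow(X), mu * phi_true, (1 - mu) * phi_true)
  pmin(pmax(y, 1e-12), 1 - 1e-12)
}

# Nearest-positive-definite repair by eigenvalue clipping: eigenvalues below
# `floor` are raised to it and the diagonal renormalized back to 1.
near_pd_correlation <- function(R, floor = 1e-6, max_frobenius = 0.05) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= floor) return(R)
  vals <- pmax(e$values, floor)
  R2 <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(R2))
  R2 <- R2 / tcrossprod(d)
  dimnames(R2) <- dimnames(R)
  if (sqrt(sum((R2 - R)^2)) > max_frobenius)
    stop("correlation matrix not repairable to positive definite within ",
         "Frobenius distance ", max_frobenius)
  R2
}

#' Generate a diagnostic-table emulation
#'
#' Draws a dataset with the statistical fingerprint of the breast-cancer
#' diagnostic table: nine continuous cytology features with the published
#' means, standard deviations ([wdbc_moments()]) and pairwise correlations
#' ([wdbc_correlations()], repaired to positive definite by eigenvalue
#' clipping); a binary diagnosis obtained by thresholding the correlated
#' latent gaussian so that about 37.3% of records are malignant; and a
#' radius-like response built as `perimeter / (2 pi)` plus gaussian noise
#' (sd 0.25), which reproduces the near-collinearity that makes the real
#' table a stress test for least squares.
#'
#' Only first and second moments are emulated; the real table's skewness,
#' strictly positive supports and discreteness are not.
#'
#' @param n records to draw (at least 20).
#' @param seed integer seed.
#' @return A [reg_dataset()] with 10 predictors (diagnosis + 9 features),
#'   gaussian family hint.
#' @export
gen_wdbc_like <- function(n, seed) {
  if (n < 20) stop("n must be at least 20")
  mom <- wdbc_moments()
  R <- near_pd_correlation(wdbc_correlations())
  set.seed(seed)
  Z <- MASS::mvrnorm(n, mu = rep(0, 10), Sigma = R)
  diagnosis <- as.integer(Z[, 1] > stats::qnorm(1 - 0.373))
  X <- sweep(sweep(Z[, -1, drop = FALSE], 2, mom$sd, "*"), 2, mom$mean, "+")
  colnames(X) <- mom$variable
  radius <- X[, "perimeter_mean"] / (2 * pi) + stats::rnorm(n, 0, 0.25)
  Xfull <- cbind(diagnosis = diagnosis, X)
  reg_dataset(Xfull, radius, "gaussian",
              provenance = sprintf("gen_wdbc_like(n = %d, seed = %d)", n, seed))
}
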