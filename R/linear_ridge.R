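#' Ordinary least squares fit
#'
#' Fits the linear model `y = X beta + eps` with an intercept by QR
#' decomposition (never an explicit inverse). Standard errors come from
#' `sigma2 (X'X)^{-1}` with `sigma2 = RSS / (n - p - 1)`; the stored
#' log-likelihood is the gaussian likelihood at the ML variance `RSS / n`,
#' the convention used for AIC/BIC.
#'
#' @param dataset a [reg_dataset()].
#' @return An object of class `linear_fit`: coefficients, `se`, `t`,
#'   `p_value`, `sigma2`, `r_squared`, `f_stat`, `loglik`, `n`, `k_params`
#'   (p + 2, counting the intercept and the residual variance), `fitted`,
#'   `residuals`.
#' @export
fit_ols <- function(dataset) {
  stopifnot(inherits(dataset, "reg_dataset"))
  check_fittable(dataset)
  X <- cbind(`(Intercept)` = 1, dataset$X)
  y <- dataset$y
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    dep <- colnames(X)[qrx$pivot[-seq_len(qrx$rank)]]
    stop("design matrix is rank deficient; dependent column(s): ",
         paste(dep, collapse = ", "))
  }
  beta <- qr.coef(qrx, y)
  fitted <- drop(X %*% beta)
  res <- y - fitted
  n <- length(y); p <- dataset$p
  rss <- sum(res^2); tss <- sum((y - mean(y))^2)
  sigma2 <- rss / (n - p - 1)
  XtX_inv <- chol2inv(qr.R(qrx))
  se <- sqrt(sigma2 * diag(XtX_inv))
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df = n - p - 1)
  r2 <- 1 - rss / tss
  f <- (tss - rss) / p / sigma2
  loglik <- -n / 2 * (log(2 * pi * rss / n) + 1)
  structure(list(label = "OLS", coefficients = beta, se = se, t = tval,
                 p_value = pval, sigma2 = sigma2, r_squared = r2,
                 f_stat = f, loglik = loglik, n = n,
                 k_params = p + 2, fitted = fitted, residuals = res),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat("Linear model (OLS), n =", x$n, "\n")
  tab <- cbind(Estimate = x$coefficients, `Std. error` = x$se,
               t = x$t, `p value` = x$p_value)
  print(signif(tab, 4))
  cat(sprintf("R-squared %.4f, F %.4g, sigma^2 %.4g\n",
              x$r_squared, x$f_stat, x$sigma2))
  invisible(x)
}

#' Ridge coefficient estimate on standardized coordinates
#'
#' Solves `(S + k I) beta = X'y` with `S = X'X` for a standardized
#' predictor matrix and a centered response. At `k = 0` this is the OLS
#' solution; as `k` grows the coefficient norm shrinks monotonically.
#'
#' @param X_std standardized predictor matrix (see
#'   [standardize_predictors()]).
#' @param y_c centered response.
#' @param k ridge constant, `k >= 0`.
#' @return Coefficient vector of length `ncol(X_std)`.
#' @export
ridge_estimate <- function(X_std, y_c, k) {
  if (k < 0) stop("ridge constant k must be >= 0")
  S <- crossprod(X_std)
  drop(solve(S + diag(k, ncol(S)), crossprod(X_std, y_c)))
}

#' Hoerl-Kennard biasing parameter
#'
#' The data-driven ridge constant `k = p sigma2 / (beta' beta)`, evaluated
#' with the OLS residual variance and the OLS coefficients on the
#' standardized (correlation-form) scale.
#'
#' @param sigma2_hat OLS residual variance estimate, `>= 0`.
#' @param beta_hat standardized-scale OLS coefficients, not all zero.
#' @param p number of predictors.
#' @return The biasing constant k.
#' @export
hoerl_kennard_k <- function(sigma2_hat, beta_hat, p) {
  bb <- sum(beta_hat^2)
  if (bb == 0) stop("coefficient vector is all zero; k is undefined")
  if (sigma2_hat < 0) stop("sigma2_hat must be >= 0")
  p * sigma2_hat / bb
}

#' Ridge mean squared error in canonical coordinates
#'
#' In the eigenbasis of `S = X'X` with eigenvalues `lambda_i` and canonical
#' coefficients `alpha_i`, the estimation MSE of the ridge estimator at
#' constant `k` is `sum_i (lambda_i sigma2 + k^2 alpha_i^2) /
#' (lambda_i + k)^2`: the variance term shrinks in k while the squared
#' bias (with the k-squared numerator, which gives the correct
#' shrink-to-zero limit `sum alpha_i^2`) grows.
#'
#' @param lambdas positive eigenvalues of the standardized cross-product.
#' @param alphas canonical (rotated) true coefficients.
#' @param sigma2 error variance.
#' @param k ridge constant, `>= 0`.
#' @return The scalar MSE.
#' @export
ridge_mse_canonical <- function(lambdas, alphas, sigma2, k) {
  if (any(lambdas <= 0)) stop("all eigenvalues must be positive")
  if (k < 0) stop("k must be >= 0")
  sum((lambdas * sigma2 + k^2 * alphas^2) / (lambdas + k)^2)
}

#' Ridge regression fit
#'
#' Standardizes the predictors to correlation form (unit-length scaling),
#' centers the response, and computes the ridge estimator
#' `(S + k I)^{-1} X'y` with `k` either fixed or chosen by the
#' Hoerl-Kennard rule from the OLS fit. Coefficients are reported on both
#' the standardized ("SC") and the raw scale; standardized standard errors
#' use the sandwich form `sigma2 (S + kI)^{-1} S (S + kI)^{-1}` of the
#' linear shrinkage estimator. The log-likelihood is the gaussian
#' likelihood at the ridge fitted values with variance `RSS(k) / n`; the
#' ridge constant is not counted as a free parameter, so `k_params = p + 2`
#' as for OLS.
#'
#' @param dataset a [reg_dataset()].
#' @param k ridge constant (`>= 0`), or `"hk"` for the Hoerl-Kennard rule.
#' @return An object of class `ridge_fit`.
#' @export
fit_ridge <- function(dataset, k = 0) {
  stopifnot(inherits(dataset, "reg_dataset"))
  check_fittable(dataset)
  ols <- fit_ols(dataset)
  std <- standardize_predictors(dataset$X)
  Xs <- std$X_std
  y <- dataset$y
  yc <- y - mean(y)
  S <- crossprod(Xs)
  eig <- eigen(S, symmetric = TRUE)
  b_ols_sc <- ridge_estimate(Xs, yc, 0)
  n <- dataset$n; p <- dataset$p
  # residuals are invariant to the linear reparameterization
  sigma2_sc <- sum((yc - Xs %*% b_ols_sc)^2) / (n - p - 1)
  if (identical(k, "hk")) k <- hoerl_kennard_k(sigma2_sc, b_ols_sc, p)
  if (!is.numeric(k) || k < 0) stop("k must be a nonnegative number or 'hk'")
  A_inv <- solve(S + diag(k, p))
  b_sc <- drop(A_inv %*% crossprod(Xs, yc))
  W <- A_inv %*% S                 # shrinkage operator: b_sc = W b_ols_sc
  b_raw <- b_sc / std$scale
  intercept <- mean(y) - sum(b_raw * std$center)
  coef_raw <- c(`(Intercept)` = intercept, b_raw)
  fitted <- intercept + drop(dataset$X %*% b_raw)
  res <- y - fitted
  rss <- sum(res^2)
  cov_sc <- sigma2_sc * A_inv %*% S %*% A_inv
  se_sc <- sqrt(diag(cov_sc))
  t_sc <- b_sc / se_sc
  p_val <- 2 * stats::pt(-abs(t_sc), df = n - p - 1)
  loglik <- -n / 2 * (log(2 * pi * rss / n) + 1)
  alphas <- drop(crossprod(eig$vectors, b_ols_sc))
  structure(list(label = "Ridge", k = k, coefficients_sc = b_sc,
                 coefficients = coef_raw, se_sc = se_sc, t_sc = t_sc,
                 p_value = p_val, S = S, eigenvalues = eig$values,
                 alphas = alphas, W = W, sigma2_ols = sigma2_sc,
                 loglik = loglik, n = n, k_params = p + 2,
                 fitted = fitted, residuals = res,
                 center = std$center, scale = std$scale),
            class = "ridge_fit")
}

#' @export
print.ridge_fit <- function(x, ...) {
  cat(sprintf("Ridge regression, k = %.6g, n = %d\n", x$k, x$n))
  tab <- cbind(`Estimate (SC)` = c(NA, x$coefficients_sc),
               Estimate = x$coefficients,
               `Std. error (SC)` = c(NA, x$se_sc),
               `t (SC)` = c(NA, x$t_sc),
               `p value` = c(NA, x$p_value))
  print(signif(tab, 4))
  invisible(x)
}
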