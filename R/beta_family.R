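#' Log density of the mean/precision beta law
#'
#' The beta density parameterized by mean `mu` and precision `phi` has
#' shapes `(mu phi, (1 - mu) phi)`, so `E(y) = mu` and
#' `var(y) = mu(1 - mu) / (1 + phi)`; equivalently
#' `phi = (1 - sigma2) / sigma2` for `sigma2 = var(y) / (mu(1 - mu))`.
#'
#' @param y value(s) strictly inside (0, 1).
#' @param mu mean(s) strictly inside (0, 1).
#' @param phi precision, > 0.
#' @return Log density, vectorized over the arguments.
#' @export
beta_logpdf <- function(y, mu, phi) {
  if (any(y <= 0) || any(y >= 1)) stop("y must lie strictly inside (0, 1)")
  if (any(mu <= 0) || any(mu >= 1)) stop("mu must lie strictly inside (0, 1)")
  if (any(phi <= 0)) stop("phi must be > 0")
  lgamma(phi) - lgamma(mu * phi) - lgamma((1 - mu) * phi) +
    (mu * phi - 1) * log(y) + ((1 - mu) * phi - 1) * log1p(-y)
}

#' Logit link and its inverse
#'
#' `link_logit` maps a mean in (0, 1) to the linear-predictor scale,
#' `inv_logit` maps back; the round trip is exact to machine precision.
#'
#' @param mu mean(s) strictly inside (0, 1).
#' @param eta any real linear predictor(s).
#' @return `link_logit`: `log(mu / (1 - mu))`; `inv_logit`:
#'   `1 / (1 + exp(-eta))`.
#' @export
link_logit <- function(mu) {
  if (any(mu <= 0) || any(mu >= 1)) stop("mu must lie strictly inside (0, 1)")
  stats::qlogis(mu)
}

#' @rdname link_logit
#' @export
inv_logit <- function(eta) stats::plogis(eta)

#' Fisher working weights of logit-link beta regression
#'
#' The diagonal of the Fisher information for the mean coefficients:
#' `w_i = phi^2 [trigamma(mu_i phi) + trigamma((1 - mu_i) phi)]
#' (mu_i (1 - mu_i))^2`, so that `X' W X` equals the expected negative
#' Hessian of the log-likelihood in the coefficients. All weights are
#' strictly positive.
#'
#' @param mu mean vector strictly inside (0, 1).
#' @param phi precision, > 0.
#' @return Positive weight vector of `length(mu)`.
#' @export
working_weights <- function(mu, phi) {
  if (any(mu <= 0) || any(mu >= 1)) stop("mu must lie strictly inside (0, 1)")
  if (phi <= 0) stop("phi must be > 0")
  phi^2 * (trigamma(mu * phi) + trigamma((1 - mu) * phi)) * (mu * (1 - mu))^2
}

# Negative log-likelihood and gradient on internally scaled coordinates.
# par = (beta_internal, log phi); X has an intercept column.
beta_nll <- function(par, X, ly, l1y) {
  p1 <- ncol(X)
  mu <- stats::plogis(drop(X %*% par[seq_len(p1)]))
  phi <- exp(par[p1 + 1L])
  -sum(lgamma(phi) - lgamma(mu * phi) - lgamma((1 - mu) * phi) +
         (mu * phi - 1) * ly + ((1 - mu) * phi - 1) * l1y)
}

beta_nll_grad <- function(par, X, ly, l1y) {
  p1 <- ncol(X)
  eta <- drop(X %*% par[seq_len(p1)])
  mu <- stats::plogis(eta)
  phi <- exp(par[p1 + 1L])
  ystar <- ly - l1y
  mustar <- digamma(mu * phi) - digamma((1 - mu) * phi)
  g_beta <- crossprod(X, phi * (ystar - mustar) * mu * (1 - mu))
  g_phi <- sum(digamma(phi) - mu * digamma(mu * phi) -
                 (1 - mu) * digamma((1 - mu) * phi) + mu * ly + (1 - mu) * l1y)
  -c(g_beta, g_phi * phi)
}

# Analytic Hessian of the negative log-likelihood in (beta, log phi).
beta_nll_hess <- function(par, X, ly, l1y) {
  p1 <- ncol(X)
  eta <- drop(X %*% par[seq_len(p1)])
  mu <- stats::plogis(eta)
  phi <- exp(par[p1 + 1L])
  m <- mu * (1 - mu)
  ystar <- ly - l1y
  t1 <- trigamma(mu * phi); t2 <- trigamma((1 - mu) * phi)
  mustar <- digamma(mu * phi) - digamma((1 - mu) * phi)
  # d2l/deta2, d2l/(deta dlogphi), d2l/dlogphi2 per observation
  h_ee <- phi * (-phi * (t1 + t2) * m^2 + (ystar - mustar) * m * (1 - 2 * mu))
  h_et <- phi * m * ((ystar - mustar) - phi * (t1 * mu - t2 * (1 - mu)))
  Dsum <- sum(digamma(phi) - mu * digamma(mu * phi) -
                (1 - mu) * digamma((1 - mu) * phi) + mu * ly + (1 - mu) * l1y)
  h_tt <- phi * Dsum +
    phi^2 * sum(trigamma(phi) - mu^2 * t1 - (1 - mu)^2 * t2)
  H <- matrix(0, p1 + 1L, p1 + 1L)
  H[seq_len(p1), seq_len(p1)] <- crossprod(X, X * h_ee)
  H[seq_len(p1), p1 + 1L] <- crossprod(X, h_et)
  H[p1 + 1L, seq_len(p1)] <- H[seq_len(p1), p1 + 1L]
  H[p1 + 1L, p1 + 1L] <- h_tt
  -H
}

#' Beta regression by maximum likelihood
#'
#' Maximizes the joint log-likelihood of the logit-link mean/precision
#' beta model in `(beta, log phi)`. Predictors are z-scaled internally
#' (the optimum is invariant; the optimizer is not), initial values come
#' from an OLS fit of `logit(y)` with a method-of-moments precision, and a
#' BFGS run with the analytic gradient is polished by damped Newton steps
#' until the score is below `tol` on the internal scale. Standard errors
#' come from the inverse observed information, mapped back to the raw
#' predictor scale.
#'
#' @param dataset a [reg_dataset()] with a unit-interval response.
#' @param tol convergence threshold for the maximum absolute score entry
#'   (internal scale; default 1e-6).
#' @param max_newton maximum Newton polish iterations.
#' @param on_fail `"error"` (default) to stop on non-convergence with the
#'   iteration trajectory attached, `"warn"` to return the best fit found.
#' @return An object of class `beta_fit`: `coefficients` (raw scale, with
#'   intercept), `phi`, `se`, `z`, `p_value`, `loglik`, `fitted` (means),
#'   `eta`, `weights` (Fisher working weights at the fit), `n`, `k_params`
#'   (p + 2, counting the intercept and phi), `converged`, `score`.
#' @export
fit_beta_ml <- function(dataset, tol = 1e-6, max_newton = 50,
                        on_fail = c("error", "warn")) {
  stopifnot(inherits(dataset, "reg_dataset"))
  on_fail <- match.arg(on_fail)
  check_fittable(dataset)
  y <- dataset$y
  if (any(y <= 0) || any(y >= 1))
    stop("beta regression requires a response strictly inside (0, 1); ",
         "see prepare_beta_response()")
  std <- standardize_predictors(dataset$X, "z_score")
  X <- cbind(`(Intercept)` = 1, std$X_std)
  p1 <- ncol(X)
  if (qr(X)$rank < p1) stop("design matrix is rank deficient")
  ly <- log(y); l1y <- log1p(-y)
  # initialization: logit-scale least squares + method-of-moments phi
  b0 <- qr.coef(qr(X), ly - l1y)
  mu0 <- stats::plogis(drop(X %*% b0))
  v0 <- stats::var(y - mu0)
  phi0 <- max(mean(mu0 * (1 - mu0)) / v0 - 1, 1e-2)
  par <- c(b0, log(phi0))
  opt <- stats::optim(par, beta_nll, beta_nll_grad, X = X, ly = ly, l1y = l1y,
                      method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-15))
  par <- opt$par
  trajectory <- data.frame(iter = 0L, nll = opt$value,
                           max_score = max(abs(beta_nll_grad(par, X, ly, l1y))))
  converged <- trajectory$max_score[1L] < tol
  it <- 0L
  while (!converged && it < max_newton) {
    it <- it + 1L
    g <- beta_nll_grad(par, X, ly, l1y)
    H <- beta_nll_hess(par, X, ly, l1y)
    step <- tryCatch(solve(H, g), error = function(e) g / max(abs(diag(H)), 1))
    f_old <- beta_nll(par, X, ly, l1y)
    g_old <- max(abs(g))
    # the objective is only trustworthy to ~|f| * 1e-10 (it sums large
    # cancelling lgamma terms); near the optimum accept any step that
    # shrinks the score norm instead
    f_tol <- 1e-10 * (abs(f_old) + 1)
    damp <- 1
    repeat {
      cand <- par - damp * step
      f_new <- beta_nll(cand, X, ly, l1y)
      ok <- is.finite(f_new) &&
        (f_new <= f_old + f_tol ||
           max(abs(beta_nll_grad(cand, X, ly, l1y))) < g_old)
      if (ok) break
      damp <- damp / 2
      if (damp < 1e-8) { cand <- par; f_new <- f_old; break }
    }
    par <- cand
    ms <- max(abs(beta_nll_grad(par, X, ly, l1y)))
    trajectory <- rbind(trajectory, data.frame(iter = it, nll = f_new,
                                               max_score = ms))
    converged <- ms < tol
  }
  if (!converged) {
    msg <- sprintf("beta ML did not converge (max |score| = %.3g after %d Newton steps)",
                   utils::tail(trajectory$max_score, 1), it)
    if (on_fail == "error") {
      err <- simpleError(msg)
      err$trajectory <- trajectory
      stop(err)
    }
    warning(msg)
  }
  H <- beta_nll_hess(par, X, ly, l1y)
  cov_int <- tryCatch(solve(H), error = function(e) MASS::ginv(H))
  # map (intercept, scaled slopes, log phi) back to the raw scale
  p <- dataset$p
  J <- diag(p1 + 1)
  J[1L, 1L + seq_len(p)] <- -std$center / std$scale
  for (j in seq_len(p)) J[1L + j, 1L + j] <- 1 / std$scale[j]
  phi <- exp(par[p1 + 1L])
  phi <- unname(phi)
  J[p1 + 1L, p1 + 1L] <- phi             # delta method for phi = exp(log phi)
  cov_raw <- J %*% cov_int %*% t(J)
  beta_raw <- drop(J[seq_len(p1), seq_len(p1)] %*% par[seq_len(p1)])
  names(beta_raw) <- c("(Intercept)", dataset$column_names)
  se <- sqrt(pmax(diag(cov_raw), 0))
  z <- c(beta_raw, phi) / se
  eta <- beta_raw[1L] + drop(dataset$X %*% beta_raw[-1L])
  mu <- stats::plogis(eta)
  fit <- structure(list(label = "Beta", coefficients = beta_raw, phi = phi,
                        se = se[seq_len(p1)], se_phi = se[p1 + 1L],
                        z = z[seq_len(p1)], p_value = 2 * stats::pnorm(-abs(z[seq_len(p1)])),
                        loglik = -utils::tail(trajectory$nll, 1L),
                        fitted = mu, eta = eta,
                        weights = working_weights(mu, phi),
                        n = dataset$n, k_params = p + 2,
                        X = cbind(`(Intercept)` = 1, dataset$X), y = y,
                        converged = converged,
                        score = utils::tail(trajectory$max_score, 1L),
                        trajectory = trajectory),
                   class = "beta_fit")
  fit$deviance_residuals <- beta_deviance_residuals(fit)
  fit
}

#' @export
print.beta_fit <- function(x, ...) {
  cat("Beta regression (ML), n =", x$n, "\n")
  tab <- cbind(Estimate = x$coefficients, `Std. error` = x$se,
               z = x$z, `p value` = x$p_value)
  print(signif(tab, 4))
  cat(sprintf("phi %.6g, log-likelihood %.4f\n", x$phi, x$loglik))
  invisible(x)
}

#' Beta ridge regression
#'
#' Shrinks the maximum-likelihood beta-regression coefficients towards
#' zero through the Fisher working-weight matrix evaluated at the ML fit:
#' `beta_BRR = (X'WX + k I)^{-1} X'WX beta_ML`, the minimizer of the
#' ridge Lagrangian built on the weighted sum of squared errors. The
#' precision is held at its ML estimate; the stored log-likelihood is
#' evaluated at `(beta_BRR, phi_ML)` and `k_params` stays `p + 2`.
#'
#' @param dataset a [reg_dataset()] with a unit-interval response.
#' @param k shrinkage constant (`>= 0`), or `"hk"` for the Hoerl-Kennard
#'   analogue `k = (p + 1) / (beta_ML' beta_ML)` (unit dispersion on the
#'   link scale).
#' @param ml_fit optionally a precomputed [fit_beta_ml()] result for the
#'   same dataset.
#' @return An object of class `beta_ridge_fit`: `coefficients`
#'   (`beta_BRR`), `k`, `ml_fit`, `theta_min` and `theta_at_fit` (the
#'   weighted-SSE decomposition), `loglik`, `fitted`, `n`, `k_params`.
#' @export
fit_beta_ridge <- function(dataset, k = 0, ml_fit = NULL) {
  stopifnot(inherits(dataset, "reg_dataset"))
  if (is.null(ml_fit)) ml_fit <- fit_beta_ml(dataset)
  stopifnot(inherits(ml_fit, "beta_fit"))
  b_ml <- ml_fit$coefficients
  if (identical(k, "hk")) k <- length(b_ml) / sum(b_ml^2)
  if (!is.numeric(k) || k < 0) stop("k must be a nonnegative number or 'hk'")
  X <- ml_fit$X
  A <- crossprod(X * sqrt(ml_fit$weights))            # X'WX at the ML fit
  b <- drop(solve(A + diag(k, ncol(A)), A %*% b_ml))
  names(b) <- names(b_ml)
  eta <- drop(X %*% b)
  mu <- stats::plogis(eta)
  loglik <- sum(beta_logpdf(ml_fit$y, mu, ml_fit$phi))
  resid_ml <- ml_fit$y - ml_fit$fitted
  theta_min <- sum(ml_fit$weights * resid_ml^2)
  d <- b - b_ml
  theta_at_fit <- theta_min + drop(t(d) %*% A %*% d)
  structure(list(label = "Beta Ridge", k = k, coefficients = b,
                 ml_fit = ml_fit, XtWX = A, theta_min = theta_min,
                 theta_at_fit = theta_at_fit, loglik = loglik,
                 fitted = mu, n = ml_fit$n, k_params = ml_fit$k_params),
            class = "beta_ridge_fit")
}

#' @export
print.beta_ridge_fit <- function(x, ...) {
  cat(sprintf("Beta ridge regression, k = %.6g, n = %d\n", x$k, x$n))
  print(signif(cbind(Estimate = x$coefficients), 4))
  cat(sprintf("phi (held at ML) %.6g, log-likelihood %.4f\n",
              x$ml_fit$phi, x$loglik))
  invisible(x)
}

#' Deviance residuals of a beta regression fit
#'
#' Signed square roots of each record's contribution to twice the
#' log-likelihood gap between the saturated model and the fit, with the
#' sign of `y - mu`. The saturated log-likelihood is evaluated at the
#' exact per-observation maximizing mean -- the solution of
#' `psi(mu phi) - psi((1 - mu) phi) = logit(y)`, which coincides with the
#' usual `mu = y` convention up to O(1/phi) but stays well defined for
#' observations within machine precision of the boundary. Squared
#' deviances below -1e-10 (impossible up to floating point) raise an
#' error; tinier negatives are clipped to zero.
#'
#' @param fit a [fit_beta_ml()] result.
#' @return Residual vector of length `n`.
#' @export
beta_deviance_residuals <- function(fit) {
  stopifnot(inherits(fit, "beta_fit"))
  y <- fit$y; mu <- fit$fitted; phi <- fit$phi
  ystar <- log(y) - log1p(-y)
  # saturated mean by safeguarded Newton on the logit scale
  m <- ystar
  for (it in 1:100) {
    ms <- stats::plogis(m)
    h <- digamma(ms * phi) - digamma((1 - ms) * phi) - ystar
    hp <- phi * (trigamma(ms * phi) + trigamma((1 - ms) * phi)) * ms * (1 - ms)
    step <- pmax(pmin(h / hp, 5), -5)
    m <- m - step
    if (max(abs(step)) < 1e-12) break
  }
  mu_sat <- stats::plogis(m)
  d2 <- 2 * (beta_logpdf(y, mu_sat, phi) - beta_logpdf(y, mu, phi))
  if (any(d2 < -1e-10))
    stop("negative squared deviance beyond tolerance: ", min(d2))
  sign(y - mu) * sqrt(pmax(d2, 0))
}
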