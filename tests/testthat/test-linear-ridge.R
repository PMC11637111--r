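test_that("OLS reproduces exact linear data and basic identities", {
  set.seed(1)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- 2 + drop(X %*% c(1, -2, 0.5))
  fit <- fit_ols(reg_dataset(X, y))
  expect_lt(max(abs(fit$residuals)), 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  ds <- make_gaussian_dataset()
  fit2 <- fit_ols(ds)
  expect_lt(abs(sum(fit2$residuals)), 1e-8 * ds$n)
  expect_gte(fit2$r_squared, 0); expect_lte(fit2$r_squared, 1)
  expect_gte(fit2$f_stat, 0)
  # rank deficiency names the dependent column
  X2 <- cbind(X, d = X[, "a"] + X[, "b"])
  expect_error(fit_ols(reg_dataset(X2, rnorm(20))), "d")
})

test_that("ridge_estimate solves the normal equations and shrinks", {
  ds <- make_gaussian_dataset(n = 60)
  std <- standardize_predictors(ds$X)
  yc <- ds$y - mean(ds$y)
  b0 <- ridge_estimate(std$X_std, yc, 0)
  b_ols <- qr.coef(qr(std$X_std), yc)
  expect_equal(unname(b0), unname(b_ols), tolerance = 1e-10)
  # orthonormal design: closed-form shrinkage by 1/(1 + k)
  Q <- qr.Q(qr(matrix(rnorm(80), 40, 2)))
  yq <- drop(Q %*% c(1, 2))
  expect_equal(ridge_estimate(Q, yq, 1), c(0.5, 1.0), tolerance = 1e-10)
  expect_error(ridge_estimate(Q, yq, -0.1), "k")
})

test_that("ridge_estimate agrees with brute-force minimization of the objective", {
  # penalized least-squares objective: ||y - Xb||^2 + k b'b (the constant
  # c in the Lagrangian does not move the argmin)
  for (i in 1:10) {
    set.seed(400 + i)
    n <- 30; p <- 4; k <- runif(1, 0.05, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    obj <- function(b) sum((y - X %*% b)^2) + k * sum(b^2)
    grad <- function(b) drop(-2 * crossprod(X, y - X %*% b) + 2 * k * b)
    opt <- optim(rep(0, p), obj, grad, method = "BFGS",
                 control = list(maxit = 1000, reltol = 1e-15))
    expect_equal(unname(ridge_estimate(X, y, k)), opt$par, tolerance = 1e-6)
  }
})

test_that("the Hoerl-Kennard rule has its defining arithmetic and benefit", {
  expect_equal(hoerl_kennard_k(0, c(1, 2), 2), 0)
  expect_equal(hoerl_kennard_k(1, c(1, 1), 2), 1)
  expect_error(hoerl_kennard_k(1, c(0, 0), 2), "zero")
  # under collinearity the HK ridge beats OLS in estimation MSE
  set.seed(42)
  n <- 100; p <- 4
  R <- gen_correlation_matrix(p, 0.9)
  X <- MASS::mvrnorm(n, rep(0, p), R)
  std <- standardize_predictors(X)
  Xs <- std$X_std
  beta_true <- c(1, -1, 0.5, 0.5)
  beta_sc <- beta_true * std$scale     # truth on the standardized scale
  sigma <- 2
  S <- crossprod(Xs)
  mse <- matrix(NA_real_, 500, 2)
  for (r in 1:500) {
    yc <- drop(Xs %*% beta_sc) + rnorm(n, 0, sigma)
    yc <- yc - mean(yc)
    b_ols <- ridge_estimate(Xs, yc, 0)
    s2 <- sum((yc - Xs %*% b_ols)^2) / (n - p - 1)
    b_hk <- ridge_estimate(Xs, yc, hoerl_kennard_k(s2, b_ols, p))
    mse[r, ] <- c(sum((b_ols - beta_sc)^2), sum((b_hk - beta_sc)^2))
  }
  expect_lt(mean(mse[, 2]), mean(mse[, 1]))
})

test_that("canonical ridge MSE has its limits and Monte-Carlo expectation", {
  lam <- c(2, 1, 0.1); sig2 <- 0.5
  al <- c(1, 1, 1)
  expect_equal(ridge_mse_canonical(lam, al, sig2, 0), sum(sig2 / lam))
  expect_equal(ridge_mse_canonical(lam, al, 1e9, 0) * 0 +
                 ridge_mse_canonical(lam, al, sig2, 1e9), sum(al^2),
               tolerance = 1e-6)
  expect_error(ridge_mse_canonical(c(1, -1), al[1:2], sig2, 0.1), "positive")
  # Monte-Carlo expectation oracle in canonical coordinates:
  # bhat_i(k) = (lambda_i alpha_i + z_i) / (lambda_i + k), z_i ~ N(0, sig2 lambda_i)
  k <- 0.5; al2 <- c(0.8, -0.4, 1.2)
  set.seed(99)
  N <- 2e4
  draws <- vapply(seq_along(lam), function(i) {
    z <- rnorm(N, 0, sqrt(sig2 * lam[i]))
    ((lam[i] * al2[i] + z) / (lam[i] + k) - al2[i])^2
  }, numeric(N))
  tot <- rowSums(draws)
  mc_se <- sd(tot) / sqrt(N)
  expect_lt(abs(ridge_mse_canonical(lam, al2, sig2, k) - mean(tot)), 3 * mc_se)
  # existence of an improving k when any alpha is nonzero
  ks <- seq(0, 2, by = 1e-4)
  vals <- vapply(ks, function(k) ridge_mse_canonical(lam, al2, sig2, k),
                 numeric(1))
  expect_lte(min(vals), vals[1])
  expect_lt(max(abs(diff(vals))), 0.05)  # continuity on a fine grid
})

test_that("fit_ridge reduces to OLS at k = 0 and shrinks monotonically", {
  ds <- make_gaussian_dataset(n = 90)
  r0 <- fit_ridge(ds, k = 0)
  ols <- fit_ols(ds)
  expect_equal(r0$coefficients, ols$coefficients, tolerance = 1e-8)
  expect_equal(r0$loglik, ols$loglik, tolerance = 1e-8)
  norms <- vapply(c(0, 0.01, 0.1, 1), function(k)
    sqrt(sum(fit_ridge(ds, k = k)$coefficients_sc^2)), numeric(1))
  expect_true(all(diff(norms) < 0))
  expect_error(fit_ridge(ds, k = -1), "k")
})

test_that("the emulated diagnostic table gives perimeter the dominant ridge term", {
  ds <- gen_wdbc_like(500, seed = 31)
  rr <- fit_ridge(ds, k = "hk")
  expect_gt(rr$k, 0)
  expect_identical(names(which.max(abs(rr$coefficients_sc))), "perimeter_mean")
})
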