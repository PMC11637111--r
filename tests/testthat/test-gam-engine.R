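test_that("the CRS penalty annihilates linear functions and has rank k - 2", {
  set.seed(4)
  x <- sort(runif(80))
  bs <- build_crs_basis(x, k_basis = 8, absorb_constraint = FALSE)
  # coefficients of a cr smooth are function values at the knots
  beta_lin <- 2 * bs$knots + 1
  expect_lt(drop(t(beta_lin) %*% bs$penalty %*% beta_lin),
            1e-10 * max(abs(bs$penalty)))
  ev <- eigen(bs$penalty, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(ev < 1e-8 * max(ev)), 2)
  expect_true(all(ev[1:6] > 0))
  # interpolation: the basis evaluated at the knots returns the knot values
  bs_k <- build_crs_basis(bs$knots, k_basis = 8, absorb_constraint = FALSE)
  vals <- rnorm(8)
  expect_equal(drop(bs_k$basis %*% vals), vals, tolerance = 1e-8)
  # constrained basis loses one column
  bc <- build_crs_basis(x, k_basis = 8)
  expect_equal(ncol(bc$basis), 7)
  expect_error(build_crs_basis(rep(1:3, 10), k_basis = 8), "distinct")
})

test_that("penalized_loglik is plain arithmetic on its blocks", {
  S <- diag(2)
  expect_equal(penalized_loglik(c(1, 1), 0, S, -5), -5)
  expect_equal(penalized_loglik(c(1, 1), 2, S, -10), -10 - 0.5 * 2 * 2)
  Snull <- matrix(0, 2, 2)
  expect_equal(penalized_loglik(c(3, -2), 7, Snull, -4), -4)
  expect_error(penalized_loglik(c(1, 1), -1, S, 0), "lambda")
})

test_that("a smooth-free GAM reduces to the parametric fits", {
  ds <- make_gaussian_dataset(n = 100)
  g <- fit_gam(ds, family = "gaussian")
  ols <- fit_ols(ds)
  expect_equal(unname(g$coefficients), unname(ols$coefficients),
               tolerance = 1e-8)
  expect_equal(g$edf, ds$p + 1, tolerance = 1e-8)
  expect_equal(g$loglik, ols$loglik, tolerance = 1e-8)
  db <- make_beta_dataset(n = 300, seed = 41)
  gb <- fit_gam(db, family = "beta")
  bml <- fit_beta_ml(db)
  expect_equal(unname(gb$coefficients), unname(bml$coefficients),
               tolerance = 1e-6)
})

test_that("fixed-lambda gaussian fits match the closed-form penalized solution", {
  set.seed(8)
  n <- 150
  x <- runif(n)
  y <- sin(2 * pi * x) + rnorm(n, 0, 0.2)
  ds <- reg_dataset(cbind(x = x), y)
  lam <- 0.7
  g <- fit_gam(ds, smooth = "x", k_basis = 8, sp = lam)
  X <- g$model_matrix
  P <- crossprod(X)
  bl <- g$penalty_blocks[[1]]
  P[bl$idx, bl$idx] <- P[bl$idx, bl$idx] + lam * bl$S
  b_closed <- solve(P, crossprod(X, y))
  expect_equal(unname(g$coefficients), unname(drop(b_closed)),
               tolerance = 1e-8)
  expect_lte(g$penalized_loglik, g$loglik)
})

test_that("REML smoothing recovers a smooth signal", {
  hits <- vapply(1:10, function(s) {
    set.seed(900 + s)
    n <- 500
    x <- runif(n)
    y <- sin(2 * pi * x) + rnorm(n, 0, 0.1)
    g <- fit_gam(reg_dataset(cbind(x = x), y), smooth = "x", k_basis = 10)
    cor(g$fitted, sin(2 * pi * x)) > 0.98
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("effective degrees of freedom follow the trace formula", {
  set.seed(12)
  n <- 200
  x1 <- runif(n); x2 <- runif(n)
  y <- sin(2 * pi * x1) + x2 + rnorm(n, 0, 0.2)
  ds <- reg_dataset(cbind(x1 = x1, x2 = x2), y)
  g00 <- fit_gam(ds, smooth = c("x1", "x2"), k_basis = 6, sp = c(0, 0))
  expect_equal(g00$edf, length(g00$coefficients), tolerance = 1e-6)
  g <- fit_gam(ds, smooth = c("x1", "x2"), k_basis = 6)
  expect_equal(g$edf, sum(g$engine$edf), tolerance = 1e-3)  # mgcv cross-check
  expect_lte(g$edf, length(g$coefficients))
  ginf <- fit_gam(ds, smooth = "x1", k_basis = 8, sp = 1e12)
  expect_equal(unname(ginf$edf_by_term["s(x1)"]), 1, tolerance = 0.05)
  # monotone in lambda
  edfs <- vapply(c(0.01, 0.1, 1, 10, 100), function(l)
    fit_gam(ds, smooth = "x1", k_basis = 8, sp = l)$edf, numeric(1))
  expect_true(all(diff(edfs) < 0))
})

test_that("prediction is self-consistent and respects the response scale", {
  ds <- make_gaussian_dataset(n = 100)
  g <- fit_gam(ds, smooth = "x1", k_basis = 6)
  expect_equal(predict(g, ds$X), g$fitted, tolerance = 1e-10)
  db <- make_beta_dataset(n = 200, seed = 55)
  gb <- fit_gam(db, smooth = "x1", k_basis = 6, family = "beta")
  pb <- predict(gb, db$X)
  expect_true(all(pb > 0 & pb < 1))
  g0 <- fit_gam(ds, family = "gaussian")
  ols <- fit_ols(ds)
  expect_equal(predict(g0, ds$X), ols$fitted, tolerance = 1e-8)
  nd <- ds$X; nd[1, 1] <- max(ds$X[, 1]) + 10
  expect_warning(predict(g, nd), "extrapolating")
  expect_error(predict(g, ds$X[, -1, drop = FALSE]), "column")
})

test_that("the beta additive model needs a unit-interval response", {
  ds <- make_gaussian_dataset(n = 60)
  expect_error(fit_gam(ds, family = "beta"), "strictly inside")
  expect_error(fit_gam(make_beta_dataset(), smooth = "nope"), "nope")
})
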