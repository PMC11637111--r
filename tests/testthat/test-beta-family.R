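test_that("the beta log density normalizes and matches the two-shape form", {
  expect_equal(beta_logpdf(0.73, 0.5, 2), 0)          # uniform case
  q <- integrate(function(y) exp(beta_logpdf(y, 0.3, 5)), 0, 1,
                 rel.tol = 1e-12)
  expect_equal(q$value, 1, tolerance = 1e-8)
  expect_equal(beta_logpdf(0.3, 0.3, 5),
               dbeta(0.3, 0.3 * 5, 0.7 * 5, log = TRUE))
  expect_error(beta_logpdf(1.2, 0.5, 2), "y")
  expect_error(beta_logpdf(0.5, 0, 2), "mu")
  expect_error(beta_logpdf(0.5, 0.5, -2), "phi")
})

test_that("the logit link round-trips to machine precision", {
  expect_equal(link_logit(0.5), 0)
  expect_equal(inv_logit(3), 0.95257, tolerance = 5e-6)
  expect_equal(inv_logit(link_logit(0.137)), 0.137, tolerance = 1e-12)
  expect_error(link_logit(1), "mu")
})

test_that("working weights are the Fisher information weights", {
  w <- working_weights(rep(0.5, 4), 2)
  expect_true(all(w == w[1]))
  set.seed(5)
  mu <- runif(10000, 0.01, 0.99); phi <- runif(10000, 0.1, 50)
  expect_true(all(working_weights(mu, phi[1]) > 0))
  # X'WX matches the finite-difference negative Hessian in beta at an ML
  # fit. The comparison point is data with zero per-observation score
  # (y solving logit(y) = psi(mu phi) - psi((1 - mu) phi)), where the
  # chosen beta IS the ML optimum and observed and expected information
  # coincide, so the identity is exact up to differencing error.
  set.seed(13)
  X <- cbind(1, matrix(rnorm(300), 150, 2))
  b <- c(0.2, 0.5, -0.4); phi_w <- 8
  mu_fit <- plogis(drop(X %*% b))
  y_fit <- plogis(digamma(mu_fit * phi_w) - digamma((1 - mu_fit) * phi_w))
  nll_beta <- function(bb) -sum(beta_logpdf(y_fit, plogis(drop(X %*% bb)),
                                            phi_w))
  score <- crossprod(X, phi_w * ((log(y_fit) - log1p(-y_fit)) -
    (digamma(mu_fit * phi_w) - digamma((1 - mu_fit) * phi_w))) *
      mu_fit * (1 - mu_fit))
  expect_lt(max(abs(score)), 1e-10)      # b is the ML optimum for y_fit
  H_fd <- optimHess(b, nll_beta)
  XtWX <- crossprod(X * sqrt(working_weights(mu_fit, phi_w)))
  expect_lt(max(abs(H_fd - XtWX)) / max(abs(XtWX)), 1e-4)
})

test_that("beta ML converges to the optimum and recovers the truth", {
  ds <- make_beta_dataset(n = 2000, beta = c(-1, 0.5), phi = 15, seed = 1)
  fit <- fit_beta_ml(ds)
  expect_true(fit$converged)
  expect_lt(fit$score, 1e-6)
  expect_true(all(fit$fitted > 0 & fit$fitted < 1))
  expect_gt(fit$phi, 0)
  # the ML optimum beats the generating parameters on the same sample
  ll_truth <- sum(beta_logpdf(ds$y, plogis(-1 + 0.5 * ds$X[, 1]), 15))
  expect_gte(fit$loglik, ll_truth)
  # estimates near truth across a handful of seeds
  hits <- vapply(1:10, function(s) {
    d <- make_beta_dataset(n = 2000, beta = c(-1, 0.5), phi = 15,
                           seed = 600 + s)
    f <- fit_beta_ml(d)
    all(abs(f$coefficients - c(-1, 0.5)) < 3 * f$se)
  }, logical(1))
  expect_gte(sum(hits), 9)
  # likelihood ascent over accepted iterations (up to objective noise)
  expect_true(all(diff(fit$trajectory$nll) <= 1e-6 * abs(fit$trajectory$nll[1])))
})

test_that("beta ML agrees with an independent penalized-likelihood engine", {
  ds <- make_beta_dataset(n = 500, seed = 23)
  fit <- fit_beta_ml(ds)
  dat <- data.frame(y = ds$y, ds$X)
  g <- mgcv::gam(y ~ x1 + x2, data = dat,
                 family = mgcv::betar(link = "logit"), method = "ML")
  expect_equal(unname(fit$coefficients), unname(coef(g)), tolerance = 1e-5)
  expect_equal(fit$phi, g$family$getTheta(trans = TRUE), tolerance = 1e-3)
})

test_that("beta ridge interpolates between the ML fit and zero", {
  ds <- make_beta_dataset(n = 150, seed = 3)
  ml <- fit_beta_ml(ds)
  b0 <- fit_beta_ridge(ds, k = 0, ml_fit = ml)
  expect_equal(b0$coefficients, ml$coefficients, tolerance = 1e-8)
  expect_equal(b0$loglik, ml$loglik, tolerance = 1e-6)
  binf <- fit_beta_ridge(ds, k = 1e9, ml_fit = ml)
  expect_lt(max(abs(binf$coefficients)), 1e-6)
  ks <- c(0, 0.001, 0.01, 0.1, 1, 10)
  norms <- vapply(ks, function(k)
    sqrt(sum(fit_beta_ridge(ds, k = k, ml_fit = ml)$coefficients^2)),
    numeric(1))
  expect_true(all(diff(norms) <= 1e-12))
  # continuity at 0+
  tiny <- fit_beta_ridge(ds, k = 1e-8, ml_fit = ml)
  expect_lt(max(abs(tiny$coefficients - ml$coefficients)), 1e-5)
  expect_error(fit_beta_ridge(ds, k = -1, ml_fit = ml), "k")
})

test_that("beta ridge solves the weighted ridge Lagrangian", {
  ds <- make_beta_dataset(n = 80, seed = 17)
  ml <- fit_beta_ml(ds)
  k <- 0.2
  fit <- fit_beta_ridge(ds, k = k, ml_fit = ml)
  A <- crossprod(ml$X * sqrt(ml$weights))
  rho_obj <- function(b) sum(b^2) +
    (1 / k) * drop(t(b - ml$coefficients) %*% A %*% (b - ml$coefficients))
  opt <- optim(ml$coefficients, rho_obj, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-15))
  expect_equal(unname(fit$coefficients), unname(opt$par), tolerance = 1e-6)
  # the weighted-SSE decomposition is reported and ordered
  expect_gte(fit$theta_at_fit, fit$theta_min)
})

test_that("deviance residuals carry the sign of y - mu and the deviance identity", {
  ds <- make_beta_dataset(n = 300, seed = 29)
  fit <- fit_beta_ml(ds)
  r <- fit$deviance_residuals
  expect_true(all(sign(r) == sign(ds$y - fit$fitted) | r == 0))
  # a record fitted exactly has zero residual
  fake <- structure(list(y = ds$y, fitted = ds$y, phi = fit$phi),
                    class = "beta_fit")
  expect_true(all(beta_deviance_residuals(fake) == 0))
  # sum of squares equals the deviance computed from the two log-likelihoods
  ystar <- log(ds$y) - log1p(-ds$y)
  bracket <- range(ystar) + c(-5, 5)
  mu_sat <- vapply(seq_along(ds$y), function(i)
    plogis(uniroot(function(m)
      digamma(plogis(m) * fit$phi) - digamma((1 - plogis(m)) * fit$phi) -
        ystar[i], bracket, tol = 1e-12)$root), numeric(1))
  D <- 2 * (sum(beta_logpdf(ds$y, mu_sat, fit$phi)) - fit$loglik)
  expect_equal(sum(r^2), D, tolerance = 1e-8)
  # roughly symmetric around zero on emulated diagnostic data
  dw <- gen_wdbc_like(400, seed = 77)
  fw <- fit_beta_ml(reg_dataset(dw$X, prepare_beta_response(dw$y, 100),
                                "unit_interval"))
  expect_lt(abs(mean(fw$deviance_residuals)), 0.1)
})
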