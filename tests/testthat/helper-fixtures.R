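# Small synthetic problems shared across the test files.

# moderate logit-linear beta dataset
make_beta_dataset <- function(n = 200, beta = c(0.2, 0.4, -0.3), phi = 15,
                              seed = 11) {
  set.seed(seed)
  p <- length(beta) - 1
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  mu <- plogis(beta[1] + drop(X %*% beta[-1]))
  y <- rbeta(n, mu * phi, (1 - mu) * phi)
  y <- pmin(pmax(y, 1e-12), 1 - 1e-12)
  reg_dataset(X, y, "unit_interval", provenance = "helper")
}

# gaussian dataset with known linear signal
make_gaussian_dataset <- function(n = 120, beta = c(1, 0.5, -1, 0.25),
                                  sigma = 0.3, seed = 7) {
  set.seed(seed)
  p <- length(beta) - 1
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  y <- beta[1] + drop(X %*% beta[-1]) + rnorm(n, 0, sigma)
  reg_dataset(X, y, "gaussian", provenance = "helper")
}

# matrix whose *sample* correlation equals R exactly: whiten empirically,
# then color by chol(R)
make_exact_correlation_data <- function(n, R, seed = 1) {
  p <- ncol(R)
  set.seed(seed)
  Z <- matrix(rnorm(n * p), n, p)
  Z <- scale(Z, center = TRUE, scale = FALSE)
  Z <- Z %*% solve(chol(stats::cov(Z)))
  X <- Z %*% chol(R)
  colnames(X) <- paste0("v", seq_len(p))
  X
}

wdbc_predictor_names <- function() c("diagnosis", wdbc_moments()$variable)

load_wdbc_fixture <- function() {
  load_table(wdbc_path(), "radius_mean", wdbc_predictor_names())
}
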