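MODEL_LABELS <- c("GAM", "Beta", "GAM Beta", "Ridge", "Beta Ridge")

# Deterministic seed derivation: mixes a master seed with counters into
# [1, 2^31 - 2]. rho is folded in as round(100 * rho) so the same cell
# always maps to the same stream; the ridge constant is deliberately not
# part of the key, so every k sees identical data within a cell.
derive_seed <- function(master, ...) {
  parts <- c(as.numeric(master), as.numeric(c(...)))
  s <- 0
  for (v in parts) s <- (s * 69069 + v + 1) %% 2147483647
  as.integer(s %% 2147483646 + 1)
}

# Fit the five models to one simulated dataset and return their criteria.
# The beta ML fit is reused by the beta ridge fit; failures yield NA rows.
fit_five_models <- function(X, y, ridge_k, k_basis = 6) {
  n <- nrow(X)
  ds <- reg_dataset(X, y, "unit_interval", provenance = "simulation")
  smooth_all <- colnames(X)
  rec <- function(label, fit) {
    if (inherits(fit, "try-error") || is.null(fit))
      data.frame(model = label, aic = NA_real_, bic = NA_real_,
                 converged = FALSE)
    else
      data.frame(model = label, aic = aic(fit$loglik, fit$k_params),
                 bic = bic(fit$loglik, fit$k_params, n), converged = TRUE)
  }
  gam_g <- try(fit_gam(ds, smooth = smooth_all, k_basis = k_basis,
                       family = "gaussian"), silent = TRUE)
  beta_ml <- try(fit_beta_ml(ds), silent = TRUE)
  gam_b <- try(fit_gam(ds, smooth = smooth_all, k_basis = k_basis,
                       family = "beta"), silent = TRUE)
  ridge <- try(fit_ridge(ds, k = ridge_k), silent = TRUE)
  brr <- if (inherits(beta_ml, "beta_fit"))
    try(fit_beta_ridge(ds, k = ridge_k, ml_fit = beta_ml), silent = TRUE)
  else NULL
  rbind(rec("GAM", gam_g), rec("Beta", beta_ml), rec("GAM Beta", gam_b),
        rec("Ridge", ridge), rec("Beta Ridge", brr))
}

#' Run one Monte-Carlo replicate
#'
#' Generates one dataset under the configured data-generating process and
#' fits all five models: the gaussian additive model with cubic-spline
#' smooths on every predictor, parametric beta regression, the beta
#' additive model, ridge regression at the configured constant, and beta
#' ridge regression at the same constant. Non-converged fits are recorded
#' as missing, never fabricated.
#'
#' @param config a [simulation_config()].
#' @param rep_seed integer seed for this replicate; predictor and
#'   response streams are derived from it.
#' @param k_basis spline basis dimension per smooth (default 6).
#' @return A data.frame with one row per model: `model`, `aic`, `bic`,
#'   `converged`.
#' @export
run_single_rep <- function(config, rep_seed, k_basis = 6) {
  stopifnot(inherits(config, "simulation_config"))
  cfg_x <- config
  cfg_x$seed <- derive_seed(rep_seed, 1)
  X <- gen_mc_predictors(cfg_x)
  y <- gen_beta_response(X, config$beta_true, config$phi_true,
                         seed = derive_seed(rep_seed, 2))
  cbind(fit_five_models(X, y, config$ridge_k, k_basis),
        rep_seed = rep_seed)
}

#' Replicated Monte-Carlo estimates for one simulation cell
#'
#' Repeats [run_single_rep()] `config$reps` times with replicate seeds
#' derived from the master seed and the cell key `(n, rho)` -- the ridge
#' constant does not enter the seed, so the non-shrinkage models see
#' identical data across ridge constants -- and averages AIC and BIC per
#' model over the converged replicates.
#'
#' @param config a [simulation_config()] with `reps >= 2`.
#' @param k_basis spline basis dimension per smooth.
#' @return An object of class `simulation_result`: a data.frame with one
#'   row per model (`n`, `rho`, `k`, `model`, `mean_aic`, `mean_bic`,
#'   `se_aic`, `se_bic`, `n_converged`); a warning attribute flags cells
#'   with more than 20% non-convergence.
#' @export
run_mc <- function(config, k_basis = 6) {
  stopifnot(inherits(config, "simulation_config"), config$reps >= 2)
  recs <- lapply(seq_len(config$reps), function(r)
    run_single_rep(config,
                   derive_seed(config$seed, config$n,
                               round(100 * config$rho), r),
                   k_basis = k_basis))
  summarize_cell(do.call(rbind, recs), config)
}

summarize_cell <- function(recs, config) {
  out <- do.call(rbind, lapply(MODEL_LABELS, function(m) {
    sub <- recs[recs$model == m & recs$converged, , drop = FALSE]
    nc <- nrow(sub)
    data.frame(n = config$n, rho = config$rho, k = config$ridge_k,
               model = m,
               mean_aic = if (nc) mean(sub$aic) else NA_real_,
               mean_bic = if (nc) mean(sub$bic) else NA_real_,
               se_aic = if (nc > 1) stats::sd(sub$aic) / sqrt(nc) else NA_real_,
               se_bic = if (nc > 1) stats::sd(sub$bic) / sqrt(nc) else NA_real_,
               n_converged = nc)
  }))
  frac <- min(out$n_converged) / config$reps
  if (frac < 0.8)
    attr(out, "warning") <- sprintf(
      "only %.0f%% of replicates converged for some model", 100 * frac)
  class(out) <- c("simulation_result", class(out))
  out
}

#' Monte-Carlo sweep over sample size, correlation and ridge constant
#'
#' Runs [run_mc()] for every cell of the `(n, rho, k)` grid. Within a
#' `(n, rho)` pair the replicate data are shared across ridge constants
#' (the constants only affect the shrinkage fits), so the GAM, beta and
#' GAM-beta rows repeat exactly across `k` and are computed once.
#'
#' @param n_grid,rho_grid,k_grid non-empty grids of sample sizes,
#'   exchangeable correlations and ridge constants.
#' @param reps replications per cell.
#' @param seed master seed.
#' @param p,beta_true,phi_true,D data-generating parameters, see
#'   [simulation_config()].
#' @param k_basis spline basis dimension per smooth.
#' @return Long-format data.frame, one row per (cell, model).
#' @export
mc_sweep <- function(n_grid, rho_grid, k_grid, reps = 1000, seed = 1,
                     p = 4, beta_true = c(3, rep(0.5, p)), phi_true = 15,
                     D = rep(1, p), k_basis = 6) {
  stopifnot(length(n_grid) > 0, length(rho_grid) > 0, length(k_grid) > 0)
  out <- list()
  for (n in n_grid) for (rho in rho_grid) {
    base <- simulation_config(n = n, rho = rho, p = p, D = D,
                              beta_true = beta_true, phi_true = phi_true,
                              reps = reps, ridge_k = k_grid[1], seed = seed)
    # per replicate: shared data + shared non-shrinkage fits across k
    recs_by_k <- stats::setNames(
      lapply(k_grid, function(k) vector("list", reps)), as.character(k_grid))
    for (r in seq_len(reps)) {
      rep_seed <- derive_seed(seed, n, round(100 * rho), r)
      cfg_x <- base
      cfg_x$seed <- derive_seed(rep_seed, 1)
      X <- gen_mc_predictors(cfg_x)
      y <- gen_beta_response(X, beta_true, phi_true,
                             seed = derive_seed(rep_seed, 2))
      ds <- reg_dataset(X, y, "unit_interval", provenance = "simulation")
      shared <- fit_five_models_shared(ds, k_basis)
      for (k in k_grid) {
        recs_by_k[[as.character(k)]][[r]] <-
          cbind(finish_five_models(ds, shared, k), rep_seed = rep_seed)
      }
    }
    for (k in k_grid) {
      cfg <- base; cfg$ridge_k <- k
      out[[length(out) + 1L]] <-
        summarize_cell(do.call(rbind, recs_by_k[[as.character(k)]]), cfg)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# k-invariant part of a replicate: the three non-shrinkage fits
fit_five_models_shared <- function(ds, k_basis) {
  smooth_all <- colnames(ds$X)
  list(gam_g = try(fit_gam(ds, smooth = smooth_all, k_basis = k_basis,
                           family = "gaussian"), silent = TRUE),
       beta_ml = try(fit_beta_ml(ds), silent = TRUE),
       gam_b = try(fit_gam(ds, smooth = smooth_all, k_basis = k_basis,
                           family = "beta"), silent = TRUE))
}

finish_five_models <- function(ds, shared, ridge_k) {
  n <- ds$n
  rec <- function(label, fit) {
    if (inherits(fit, "try-error") || is.null(fit))
      data.frame(model = label, aic = NA_real_, bic = NA_real_,
                 converged = FALSE)
    else
      data.frame(model = label, aic = aic(fit$loglik, fit$k_params),
                 bic = bic(fit$loglik, fit$k_params, n), converged = TRUE)
  }
  ridge <- try(fit_ridge(ds, k = ridge_k), silent = TRUE)
  brr <- if (inherits(shared$beta_ml, "beta_fit"))
    try(fit_beta_ridge(ds, k = ridge_k, ml_fit = shared$beta_ml),
        silent = TRUE)
  else NULL
  rbind(rec("GAM", shared$gam_g), rec("Beta", shared$beta_ml),
        rec("GAM Beta", shared$gam_b), rec("Ridge", ridge),
        rec("Beta Ridge", brr))
}

#' Marginal summaries of a simulation sweep
#'
#' Grand means of the per-cell mean AIC/BIC per model, marginalized over
#' the requested factors -- the aggregation behind "average criterion by
#' sample size / correlation / ridge constant" displays.
#'
#' @param results long-format output of [mc_sweep()] or rows of
#'   [run_mc()] results.
#' @param margins character vector among `"n"`, `"rho"`, `"k"`.
#' @return Data.frame of per-(model, margins) means of `mean_aic` and
#'   `mean_bic`.
#' @export
summarize_mc <- function(results, margins = "n") {
  unknown <- setdiff(margins, c("n", "rho", "k"))
  if (length(unknown)) stop("unknown margin(s): ",
                            paste(unknown, collapse = ", "))
  if (!nrow(results)) stop("empty results")
  stats::aggregate(results[c("mean_aic", "mean_bic")],
                   by = results[c("model", margins)], FUN = mean)
}
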