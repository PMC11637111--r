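#' Read a pipeline configuration
#'
#' Configurations are plain lists, optionally loaded from YAML. See
#' [run_analysis()] and [run_simulation()] for the recognized fields.
#'
#' @param config a list, or path to a YAML file.
#' @return The configuration list.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  config
}

default_predictors <- function() c("diagnosis", wdbc_moments()$variable)

#' End-to-end real-data analysis pipeline
#'
#' Loads (or generates) a diagnostic-style table, computes descriptive
#' statistics and multicollinearity diagnostics, fits the requested
#' models to the unit-scaled response, and writes every artifact as CSV
#' with a JSON manifest. All models are fitted to the same scaled
#' response `y / beta_scale` so their likelihood-based criteria are
#' comparable.
#'
#' Config fields: exactly one of `input` (CSV path) or `generator`
#' (list with `n`, `seed`) -- `response` (default `"radius_mean"`),
#' `predictors` (default: diagnosis plus the nine mean cytology
#' features), `beta_scale` (default 100), `models` (subset of
#' `"ols"`, `"ridge"`, `"beta"`, `"beta_ridge"`, `"gam"`, `"gam_beta"`;
#' default all), `ridge_k` (number or `"hk"`, default `"hk"`),
#' `gam_smooth` (character vector of variables to smooth; default none,
#' i.e. parametric additive terms), `gam_k_basis` (default 10),
#' `out_dir` (required), `seed` (default 1).
#'
#' @param config list or YAML path, see Details.
#' @return Invisibly, the manifest list (artifact paths, seed, config
#'   hash).
#' @export
run_analysis <- function(config) {
  config <- read_run_config(config)
  if (is.null(config$out_dir)) stop("config must name an out_dir")
  has_input <- !is.null(config$input)
  has_gen <- !is.null(config$generator)
  if (has_input == has_gen)
    stop("config must contain exactly one of 'input' or 'generator'")
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    written <<- c(written, path)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  response <- config$response %||% "radius_mean"
  predictors <- config$predictors %||% default_predictors()
  beta_scale <- config$beta_scale %||% 100
  models <- config$models %||% c("ols", "ridge", "beta", "beta_ridge",
                                 "gam", "gam_beta")
  ridge_k <- config$ridge_k %||% "hk"
  gam_smooth <- config$gam_smooth %||% character()
  gam_k <- config$gam_k_basis %||% 10

  ds <- stage("load", {
    if (has_input) load_table(config$input, response, predictors)
    else gen_wdbc_like(config$generator$n,
                       config$generator$seed %||% seed)
  })

  stage("descriptives", {
    vars <- cbind(ds$X, setNames(data.frame(ds$y), response))
    emit(data.frame(variable = colnames(vars), N = nrow(vars),
                    minimum = apply(vars, 2, min),
                    maximum = apply(vars, 2, max),
                    mean = colMeans(vars),
                    sd = apply(vars, 2, stats::sd)),
         "descriptives.csv")
    if ("diagnosis" %in% colnames(ds$X)) {
      d <- ds$X[, "diagnosis"]
      emit(data.frame(diagnosis = c("B", "M"),
                      frequency = c(sum(d == 0), sum(d == 1)),
                      percent = 100 * c(mean(d == 0), mean(d == 1))),
           "diagnosis_frequencies.csv")
    }
  })

  diag_rep <- stage("diagnostics", {
    rep <- collinearity_diagnostics(ds)
    emit(data.frame(variable = rownames(rep$correlation),
                    round(rep$correlation, 3), check.names = FALSE),
         "correlation_matrix.csv")
    emit(data.frame(variable = names(rep$vif), vif = rep$vif),
         "vif.csv")
    emit(data.frame(convention = c("correlation", "design"),
                    condition_number = c(rep$condition_number,
                                         rep$condition_number_design)),
         "condition_number.csv")
    rep
  })

  fits <- stage("fit", {
    y_unit <- prepare_beta_response(ds$y, beta_scale)
    ds_g <- reg_dataset(ds$X, y_unit, "gaussian", ds$provenance)
    ds_u <- reg_dataset(ds$X, y_unit, "unit_interval", ds$provenance)
    fits <- list()
    beta_ml <- NULL
    if ("ols" %in% models) fits$ols <- fit_ols(ds_g)
    if ("ridge" %in% models) fits$ridge <- fit_ridge(ds_g, k = ridge_k)
    if (any(c("beta", "beta_ridge") %in% models))
      beta_ml <- fit_beta_ml(ds_u)
    if ("beta" %in% models) fits$beta <- beta_ml
    if ("beta_ridge" %in% models)
      fits$beta_ridge <- fit_beta_ridge(ds_u, k = ridge_k, ml_fit = beta_ml)
    if ("gam" %in% models)
      fits$gam <- fit_gam(ds_g, smooth = gam_smooth, k_basis = gam_k,
                          family = "gaussian")
    if ("gam_beta" %in% models)
      fits$gam_beta <- fit_gam(ds_u, smooth = gam_smooth, k_basis = gam_k,
                               family = "beta")
    fits
  })

  stage("report", {
    for (nm in names(fits)) {
      f <- fits[[nm]]
      tab <- switch(class(f)[1],
        linear_fit = data.frame(term = names(f$coefficients),
                                estimate = f$coefficients, se = f$se,
                                t = f$t, p = f$p_value),
        ridge_fit = data.frame(term = names(f$coefficients),
                               estimate_sc = c(NA, f$coefficients_sc),
                               estimate_raw = f$coefficients,
                               se_sc = c(NA, f$se_sc),
                               t_sc = c(NA, f$t_sc),
                               p = c(NA, f$p_value)),
        beta_fit = data.frame(term = names(f$coefficients),
                              estimate = f$coefficients, se = f$se,
                              z = f$z, p = f$p_value),
        beta_ridge_fit = data.frame(term = names(f$coefficients),
                                    estimate = f$coefficients),
        gam_fit = data.frame(term = rownames(f$p_table),
                             estimate = f$p_table[, 1],
                             se = f$p_table[, 2], z = f$p_table[, 3],
                             p = f$p_table[, 4]))
      emit(tab, paste0("coefficients_", nm, ".csv"))
    }
    dev <- lapply(fits, function(f)
      if (!is.null(f$deviance_residuals)) f$deviance_residuals)
    dev <- dev[!vapply(dev, is.null, logical(1))]
    if (length(dev))
      emit(do.call(rbind, lapply(names(dev), function(nm) {
        q <- stats::quantile(dev[[nm]], c(0, .25, .5, .75, 1))
        data.frame(model = fits[[nm]]$label, minimum = q[1], q1 = q[2],
                   median = q[3], q3 = q[4], maximum = q[5])
      })), "deviance_residuals_summary.csv")
    cmp <- compare_models(fits, ds$n)
    emit(cbind(cmp$table,
               best_aic = cmp$best_aic, best_bic = cmp$best_bic),
         "model_comparison.csv")
  })

  stage("manifest", {
    cfg_path <- file.path(out_dir, "config.yaml")
    yaml::write_yaml(config, cfg_path)
    manifest <- list(artifacts = basename(written),
                     config = "config.yaml",
                     config_md5 = unname(tools::md5sum(cfg_path)),
                     seed = seed,
                     n = ds$n, provenance = ds$provenance)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(manifest)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Monte-Carlo simulation pipeline
#'
#' Runs [mc_sweep()] from a configuration and writes the long-format
#' results, a wide pivot (models by sample size, one block per
#' criterion), and marginal summaries by sample size, correlation and
#' ridge constant.
#'
#' Config fields: `n_grid`, `rho_grid`, `k_grid`, `reps`, `seed`,
#' `out_dir` (required), and optionally `p`, `beta_true`, `phi_true`,
#' `k_basis`.
#'
#' @param config list or YAML path.
#' @return Invisibly, the long-format results.
#' @export
run_simulation <- function(config) {
  config <- read_run_config(config)
  for (f in c("n_grid", "rho_grid", "k_grid", "out_dir"))
    if (is.null(config[[f]])) stop("config must name ", f)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- config$p %||% 4
  res <- mc_sweep(n_grid = config$n_grid, rho_grid = config$rho_grid,
                  k_grid = config$k_grid, reps = config$reps %||% 1000,
                  seed = config$seed %||% 1, p = p,
                  beta_true = config$beta_true %||% c(3, rep(0.5, p)),
                  phi_true = config$phi_true %||% 15,
                  k_basis = config$k_basis %||% 6)
  utils::write.csv(res, file.path(config$out_dir, "results_long.csv"),
                   row.names = FALSE)
  wide <- stats::reshape(
    res[c("rho", "k", "model", "n", "mean_aic", "mean_bic")],
    direction = "wide", idvar = c("rho", "k", "model"), timevar = "n")
  utils::write.csv(wide, file.path(config$out_dir, "results_wide.csv"),
                   row.names = FALSE)
  for (m in c("n", "rho", "k"))
    utils::write.csv(summarize_mc(res, m),
                     file.path(config$out_dir,
                               paste0("summary_by_", m, ".csv")),
                     row.names = FALSE)
  invisible(res)
}
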