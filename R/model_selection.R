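#' Information criteria
#'
#' `aic()` returns `-2 L + 2 k`; `bic()` returns `-2 L + k ln(n)`. The
#' parameter count may be real-valued (effective degrees of freedom for
#' additive models). The two criteria agree exactly when `n = e^2`.
#'
#' @param loglik log-likelihood of the fitted model.
#' @param k_params number of estimated parameters (> 0).
#' @param n number of observations (>= 1).
#' @return The criterion value.
#' @export
aic <- function(loglik, k_params) {
  stopifnot(k_params > 0)
  -2 * loglik + 2 * k_params
}

#' @rdname aic
#' @export
bic <- function(loglik, k_params, n) {
  stopifnot(k_params > 0, n >= 1)
  -2 * loglik + k_params * log(n)
}

#' Conditional AIC of a penalized additive fit
#'
#' `-2 L + 2 (edf + 1)`, with `L` the unpenalized log-likelihood at the
#' penalized estimate, `edf` the total effective degrees of freedom and
#' one additional scale/precision parameter. For a fit with no smooth
#' terms this reduces to the ordinary AIC of the parametric model.
#'
#' @param fit a [fit_gam()] result.
#' @return The conditional AIC.
#' @export
gam_conditional_aic <- function(fit) {
  stopifnot(inherits(fit, "gam_fit"))
  aic(fit$loglik, fit$edf + 1)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` comes from regressing column j
#' on all other columns plus an intercept. Perfectly collinear columns
#' report `Inf` rather than raising an error.
#'
#' @param X numeric predictor matrix with at least two columns.
#' @return Named vector of VIFs, all `>= 1`.
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("VIF needs at least two predictor columns")
  out <- vapply(seq_len(ncol(X)), function(j) {
    f <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    rss <- sum(f$residuals^2)
    tss <- sum((X[, j] - mean(X[, j]))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-14) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(out) <- colnames(X)
  out
}

#' Condition number of a predictor matrix
#'
#' Two conventions are offered. `"correlation"` returns
#' `sqrt(lambda_max / lambda_min)` of the correlation matrix of `X`.
#' `"design"` returns the Belsley condition index: the ratio of the
#' largest to the smallest singular value of the design matrix with an
#' intercept column, every column scaled to unit length -- the convention
#' under which the diagnostic is usually quoted for raw regression
#' designs, and the one the bundled diagnostic table reproduces.
#'
#' @param X numeric predictor matrix, `p >= 2`, no constant column.
#' @param type `"correlation"` (default) or `"design"`.
#' @return The condition number (`>= 1`; `Inf` for a singular matrix).
#' @export
condition_number <- function(X, type = c("correlation", "design")) {
  type <- match.arg(type)
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("need at least two predictor columns")
  if (any(apply(X, 2, stats::sd) == 0)) stop("constant column in X")
  if (type == "correlation") {
    ev <- eigen(stats::cor(X), symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) return(Inf)
    sqrt(max(ev) / min(ev))
  } else {
    Xi <- cbind(1, X)
    Xs <- sweep(Xi, 2, sqrt(colSums(Xi^2)), "/")
    d <- svd(Xs, nu = 0, nv = 0)$d
    if (min(d) <= 0) return(Inf)
    max(d) / min(d)
  }
}

#' Multicollinearity diagnostics report
#'
#' Pairwise correlations, variance inflation factors and condition
#' numbers of a predictor matrix, with the conventional flags: predictor
#' pairs with `|r| > 0.8` and variables with `VIF > 5`.
#'
#' @param x a [reg_dataset()] or numeric predictor matrix.
#' @return An object of class `diagnostics_report`.
#' @export
collinearity_diagnostics <- function(x) {
  X <- if (inherits(x, "reg_dataset")) x$X else as.matrix(x)
  R <- stats::cor(X)
  v <- vif(X)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  pairs <- which(abs(R) > 0.8 & upper.tri(R), arr.ind = TRUE)
  flag_pairs <- if (nrow(pairs)) data.frame(
    var1 = rownames(R)[pairs[, 1]], var2 = colnames(R)[pairs[, 2]],
    r = R[pairs]) else data.frame(var1 = character(), var2 = character(),
                                  r = numeric())
  structure(list(correlation = R, vif = v,
                 condition_number = condition_number(X, "correlation"),
                 condition_number_design = condition_number(X, "design"),
                 lambda_max = max(ev), lambda_min = min(ev),
                 high_correlation_pairs = flag_pairs,
                 high_vif = names(v)[is.infinite(v) | v > 5]),
            class = "diagnostics_report")
}

#' @export
print.diagnostics_report <- function(x, ...) {
  cat("Multicollinearity diagnostics\n")
  cat(sprintf("  condition number: %.3f (correlation), %.3f (design)\n",
              x$condition_number, x$condition_number_design))
  cat("  VIF:\n")
  print(round(x$vif, 3))
  if (nrow(x$high_correlation_pairs)) {
    cat("  pairs with |r| > 0.8:\n")
    print(x$high_correlation_pairs, row.names = FALSE)
  }
  if (length(x$high_vif))
    cat("  VIF > 5:", paste(x$high_vif, collapse = ", "), "\n")
  invisible(x)
}

#' Compare fitted models by AIC and BIC
#'
#' Builds the per-model criterion table and names the winner under each
#' criterion. Every fit must expose `label`, `loglik` and `k_params`
#' (effective degrees of freedom plus scale for additive fits). Ties are
#' broken by fewer parameters, then label order.
#'
#' @param fits list of fitted model objects.
#' @param n number of observations (shared across fits).
#' @return An object of class `selection_report`: a data.frame `table`
#'   with columns model/loglik/k_params/AIC/BIC, plus `best_aic` and
#'   `best_bic`.
#' @export
compare_models <- function(fits, n) {
  if (!length(fits)) stop("empty model list")
  tab <- do.call(rbind, lapply(fits, function(f) {
    data.frame(model = f$label, loglik = f$loglik, k_params = f$k_params,
               AIC = aic(f$loglik, f$k_params),
               BIC = bic(f$loglik, f$k_params, n))
  }))
  pick <- function(crit) {
    ord <- order(tab[[crit]], tab$k_params, tab$model)
    tab$model[ord[1L]]
  }
  structure(list(table = tab, best_aic = pick("AIC"), best_bic = pick("BIC"),
                 n = n),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("Model comparison (n =", x$n, ")\n")
  print(transform(x$table, loglik = round(loglik, 3), AIC = round(AIC, 3),
                  BIC = round(BIC, 3)), row.names = FALSE)
  cat("best by AIC:", x$best_aic, "| best by BIC:", x$best_bic, "\n")
  invisible(x)
}
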