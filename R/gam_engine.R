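#' Cubic regression spline basis and penalty
#'
#' Builds the cubic-regression-spline basis for one covariate, with knots
#' at evenly spaced quantiles and the integrated-squared-second-derivative
#' penalty. In this parameterization the coefficients are the function
#' values at the knots, so a straight line has zero penalty. With
#' `absorb_constraint = TRUE` (the default) the sum-to-zero
#' identifiability constraint is absorbed by reparameterization, reducing
#' the basis to `k_basis - 1` columns; without it the penalty has exactly
#' two zero eigenvalues (constant and linear null space).
#'
#' @param x covariate vector with at least `k_basis` distinct values.
#' @param k_basis basis dimension (>= 4).
#' @param absorb_constraint absorb the sum-to-zero constraint?
#' @return A list with `basis` (n x k matrix), `penalty` (k x k PSD
#'   matrix) and `knots`.
#' @export
build_crs_basis <- function(x, k_basis = 10, absorb_constraint = TRUE) {
  if (k_basis < 4) stop("k_basis must be at least 4")
  if (length(unique(x)) < k_basis)
    stop("x needs at least k_basis = ", k_basis, " distinct values")
  dat <- data.frame(x = x)
  sm <- mgcv::smoothCon(mgcv::s(x, bs = "cr", k = k_basis), data = dat,
                        absorb.cons = absorb_constraint)[[1]]
  list(basis = sm$X, penalty = sm$S[[1]], knots = sm$xp)
}

#' Penalized log-likelihood
#'
#' `L(beta) - 0.5 * sum_j lambda_j beta_j' S_j beta_j`, one smoothing
#' parameter per penalty block.
#'
#' @param beta coefficient vector, or a list of per-block coefficient
#'   vectors.
#' @param lambda nonnegative smoothing parameter(s), one per block.
#' @param S_blocks a penalty matrix or list of penalty matrices.
#' @param loglik_value unpenalized log-likelihood at `beta`.
#' @return The penalized log-likelihood.
#' @export
penalized_loglik <- function(beta, lambda, S_blocks, loglik_value) {
  if (any(lambda < 0)) stop("lambda must be nonnegative")
  if (!is.list(S_blocks)) S_blocks <- list(S_blocks)
  if (!is.list(beta)) beta <- list(beta)
  stopifnot(length(beta) == length(S_blocks),
            length(lambda) == length(S_blocks))
  pen <- sum(vapply(seq_along(S_blocks), function(j)
    lambda[j] * drop(t(beta[[j]]) %*% S_blocks[[j]] %*% beta[[j]]),
    numeric(1)))
  loglik_value - pen / 2
}

#' Penalized-regression-spline GAM fit
#'
#' Fits an additive model with cubic-regression-spline smooths for the
#' requested variables and parametric terms for the rest, for a gaussian
#' or unit-interval (beta, logit link) response. Coefficients at fixed
#' smoothing parameters come from penalized iteratively reweighted least
#' squares; the smoothing parameters themselves minimize the REML
#' criterion (its Laplace-approximate extension for the beta family)
#' unless supplied through `sp`. The engine is mgcv; the stored
#' log-likelihood is the unpenalized likelihood at the penalized estimate,
#' and `k_params` is the total effective degrees of freedom plus one
#' scale/precision parameter, the count used in the conditional AIC.
#'
#' @param dataset a [reg_dataset()]; the beta family requires a
#'   unit-interval response.
#' @param smooth character vector of predictor names to smooth (default
#'   none: all terms parametric, in which case the fit reduces to OLS or
#'   parametric beta regression).
#' @param k_basis basis dimension per smooth (scalar or named vector).
#' @param family `"gaussian"` or `"beta"`.
#' @param sp optional fixed smoothing parameters (one per smooth), in the
#'   order of `smooth`; skips REML selection.
#' @return An object of class `gam_fit`: coefficients, `lambda`, per-term
#'   and total `edf`, `loglik` (unpenalized), `penalized_loglik`, `phi`
#'   (beta) or `sigma2` (gaussian), fitted means, deviance residuals,
#'   parametric coefficient table, `n`, `k_params`, and the underlying
#'   mgcv fit in `$engine`.
#' @export
fit_gam <- function(dataset, smooth = character(), k_basis = 10,
                    family = c("gaussian", "beta"), sp = NULL) {
  stopifnot(inherits(dataset, "reg_dataset"))
  family <- match.arg(family)
  check_fittable(dataset)
  if (family == "beta" && (any(dataset$y <= 0) || any(dataset$y >= 1)))
    stop("beta family requires a response strictly inside (0, 1)")
  unknown <- setdiff(smooth, dataset$column_names)
  if (length(unknown)) stop("unknown smooth variable(s): ",
                            paste(unknown, collapse = ", "))
  kb <- if (length(k_basis) == 1L)
    stats::setNames(rep(k_basis, length(smooth)), smooth)
  else k_basis[smooth]
  terms <- vapply(dataset$column_names, function(v) {
    if (v %in% smooth) sprintf("s(%s, bs = 'cr', k = %d)", v, kb[[v]])
    else v
  }, character(1))
  fml <- stats::as.formula(paste(".response ~", paste(terms, collapse = " + ")))
  dat <- data.frame(.response = dataset$y, dataset$X, check.names = FALSE)
  fam <- if (family == "gaussian") stats::gaussian()
         else mgcv::betar(link = "logit")
  # with no penalized terms the beta fit is plain ML; REML (the Laplace
  # marginal likelihood) is only needed to select smoothing parameters
  method <- if (family == "beta" && !length(smooth)) "ML" else "REML"
  g <- tryCatch(
    mgcv::gam(fml, data = dat, family = fam, method = method, sp = sp),
    error = function(e) {
      if (method == "ML")
        mgcv::gam(fml, data = dat, family = fam, method = "REML", sp = sp)
      else stop(e)
    })
  n <- dataset$n
  fitted <- as.numeric(g$fitted.values)
  if (family == "gaussian") {
    rss <- sum((dataset$y - fitted)^2)
    sigma2 <- rss / n
    phi <- NULL
    loglik <- -n / 2 * (log(2 * pi * sigma2) + 1)
    w <- rep(1, n)
    pen_scale <- sigma2            # mgcv's sp is on the deviance scale
  } else {
    phi <- g$family$getTheta(trans = TRUE)
    sigma2 <- NULL
    loglik <- sum(beta_logpdf(dataset$y, fitted, phi))
    w <- working_weights(fitted, phi)
    pen_scale <- 1
  }
  Xm <- stats::predict(g, type = "lpmatrix")
  blocks <- lapply(g$smooth, function(sm) {
    list(label = sm$label, idx = sm$first.para:sm$last.para, S = sm$S[[1]])
  })
  # mgcv omits user-fixed smoothing parameters from g$sp
  lambda <- if (!length(blocks)) numeric(0)
            else if (!is.null(sp)) as.numeric(sp)
            else as.numeric(g$sp)
  names(lambda) <- vapply(blocks, `[[`, character(1), "label")
  pen <- 0
  if (length(blocks)) {
    cf <- stats::coef(g)
    pen <- sum(vapply(seq_along(blocks), function(j) {
      b <- cf[blocks[[j]]$idx]
      lambda[j] * drop(t(b) %*% blocks[[j]]$S %*% b)
    }, numeric(1)))
  }
  Lp <- loglik - pen / (2 * pen_scale)
  fit <- structure(list(label = if (family == "gaussian") "GAM" else "GAM Beta",
                        family = family, coefficients = stats::coef(g),
                        lambda = lambda, penalty_blocks = blocks,
                        model_matrix = Xm, weights = w,
                        loglik = loglik, penalized_loglik = Lp,
                        phi = phi, sigma2 = sigma2, fitted = fitted,
                        deviance_residuals = as.numeric(stats::residuals(g, type = "deviance")),
                        p_table = summary(g)$p.table,
                        smooth_vars = smooth, n = n,
                        train_range = apply(dataset$X, 2, range),
                        engine = g),
                   class = "gam_fit")
  ed <- effective_dof(fit)
  fit$edf <- ed$total
  fit$edf_by_term <- ed$by_term
  fit$k_params <- ed$total + 1         # one scale/precision parameter
  fit
}

#' Effective degrees of freedom of a penalized fit
#'
#' Recomputes `tau = trace[(X'WX + sum_j lambda_j S_j)^{-1} X'WX]` from
#' the stored model matrix, family working weights at convergence
#' (identity for gaussian) and penalty blocks; per-term values sum the
#' corresponding diagonal entries.
#'
#' @param fit a [fit_gam()] result.
#' @return A list with `total` and a named `by_term` vector (parametric
#'   terms pooled under `"parametric"`).
#' @export
effective_dof <- function(fit) {
  stopifnot(inherits(fit, "gam_fit"))
  X <- fit$model_matrix
  A <- crossprod(X * sqrt(fit$weights))
  P <- A
  for (j in seq_along(fit$penalty_blocks)) {
    bl <- fit$penalty_blocks[[j]]
    P[bl$idx, bl$idx] <- P[bl$idx, bl$idx] + fit$lambda[j] * bl$S
  }
  Fmat <- solve(P, A)
  d <- diag(Fmat)
  by_term <- c(parametric = sum(d))
  for (j in seq_along(fit$penalty_blocks)) {
    bl <- fit$penalty_blocks[[j]]
    by_term[bl$label] <- sum(d[bl$idx])
    by_term["parametric"] <- by_term["parametric"] - sum(d[bl$idx])
  }
  list(total = sum(d), by_term = by_term)
}

#' @export
print.gam_fit <- function(x, ...) {
  cat(sprintf("%s additive model, n = %d, total edf %.3f\n",
              x$label, x$n, x$edf))
  if (length(x$lambda))
    cat("  smoothing parameters:",
        paste(sprintf("%s = %.4g", names(x$lambda), x$lambda),
              collapse = ", "), "\n")
  cat(sprintf("  log-likelihood %.4f (penalized %.4f)\n",
              x$loglik, x$penalized_loglik))
  invisible(x)
}

#' Predict from a GAM fit
#'
#' Evaluates the additive linear predictor on new data and returns the
#' mean on the response scale (inverse logit for the beta family, so
#' predictions lie strictly inside (0, 1)). Values outside the training
#' range of a predictor are flagged with a warning.
#'
#' @param object a [fit_gam()] result.
#' @param newdata matrix or data.frame with the training predictor
#'   columns; defaults to the training data.
#' @param ... unused.
#' @return Fitted mean vector.
#' @export
predict.gam_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  nd <- as.data.frame(newdata)
  missing_cols <- setdiff(colnames(object$train_range), names(nd))
  if (length(missing_cols)) stop("unknown or missing column(s): ",
                                 paste(missing_cols, collapse = ", "))
  rng <- object$train_range
  for (v in colnames(rng))
    if (any(nd[[v]] < rng[1, v] | nd[[v]] > rng[2, v]))
      warning("extrapolating beyond the training range of ", v)
  as.numeric(stats::predict(object$engine, newdata = nd, type = "response"))
}
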