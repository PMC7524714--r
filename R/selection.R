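# LASSO path, leave-one-out cross-validation, the four-model family
# (max / minMSE / oneSE / min), post-selection OLS refits and nested-model
# comparison.

default_lambda_grid <- function(lambda_max, n = 100, ratio = 1e-4) {
  exp(seq(log(lambda_max), log(lambda_max * ratio), length.out = n))
}

as_predictor_matrix <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  X
}

#' L1-penalised (LASSO) linear regression path
#'
#' Solves `(1/2n) ||y - b0 - X b||^2 + lambda ||b||_1` over a decreasing
#' lambda grid by cyclic coordinate descent with warm starts. Predictors are
#' standardised internally to zero mean and unit (population) SD and the
#' response is centred; coefficients are reported on the original scale.
#' At `lambda = 0` the solution coincides with ordinary least squares; at
#' `lambda >= lambda_max` all coefficients are zero.
#'
#' @param X numeric predictor matrix or data frame (no missing values).
#' @param y numeric response.
#' @param lambda decreasing penalty grid; default 100 log-spaced values from
#'   `lambda_max` down to `1e-4 lambda_max`.
#' @param nlambda,lambda_min_ratio grid size and lower end (as a fraction of
#'   `lambda_max`) when `lambda` is not supplied.
#' @param tol coordinate-descent convergence tolerance (relative coefficient
#'   change per sweep).
#' @param maxit maximum coordinate-descent sweeps per lambda.
#' @return A list of class `"lasso_path"`: `beta` (p x nlambda, original
#'   scale), `intercept`, `lambda`, `lambda_max`, `df` (nonzero counts) and,
#'   after [loocv_mse()], `cv_mse` / `cv_se`.
#' @export
lasso_path <- function(X, y, lambda = NULL, nlambda = 100,
                       lambda_min_ratio = 1e-4, tol = 1e-7, maxit = 100000) {
  X <- as_predictor_matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), nrow(X) > 2)
  if (anyNA(X) || anyNA(y)) stop("missing values are not supported")
  sds <- apply(X, 2, function(col) sqrt(mean((col - mean(col))^2)))
  if (any(sds == 0))
    warning("constant predictor(s) dropped from the active set: ",
            paste(colnames(X)[sds == 0], collapse = ", "))
  if (is.null(lambda)) {
    lmax <- lasso_path_cpp(X, y, 1, tol, 1L)$lambda_max
    lambda <- default_lambda_grid(lmax, nlambda, lambda_min_ratio)
  }
  lambda <- sort(as.numeric(lambda), decreasing = TRUE)
  fit <- lasso_path_cpp(X, y, lambda, tol, as.integer(maxit))
  beta <- fit$beta
  rownames(beta) <- colnames(X)
  structure(list(beta = beta, intercept = as.numeric(fit$intercept),
                 lambda = lambda, lambda_max = fit$lambda_max,
                 df = colSums(beta != 0), X = X, y = y,
                 tol = tol, maxit = maxit),
            class = "lasso_path")
}

#' Leave-one-out cross-validated MSE along a lambda grid
#'
#' For each observation, refits the whole LASSO path on the remaining n - 1
#' observations (exactly, via rank-one downdates of the sufficient
#' statistics) and records the squared prediction error. The MSE is the mean
#' and its SE the standard deviation of the n per-observation squared errors
#' divided by `sqrt(n)`.
#'
#' @param path a [lasso_path()]; or pass `X`, `y`, `lambda` directly.
#' @param X,y,lambda used when `path` is `NULL`.
#' @return The path object augmented with `cv_mse`, `cv_se` and the index
#'   vectors `i_min` (minimum MSE) and `i_1se` (one-standard-error rule).
#' @export
loocv_mse <- function(path = NULL, X = NULL, y = NULL, lambda = NULL) {
  if (is.null(path)) path <- lasso_path(X, y, lambda = lambda)
  stopifnot(inherits(path, "lasso_path"), nrow(path$X) >= 10)
  errs <- loocv_sqerr_cpp(path$X, path$y, path$lambda, path$tol,
                          as.integer(path$maxit))
  n <- nrow(errs)
  path$cv_mse <- colMeans(errs)
  path$cv_se <- apply(errs, 2, sd) / sqrt(n)
  path$i_min <- which.min(path$cv_mse)
  thresh <- path$cv_mse[path$i_min] + path$cv_se[path$i_min]
  # largest lambda (grid is decreasing, so smallest index) within one SE
  path$i_1se <- which(path$cv_mse <= thresh)[1]
  path
}

support_at <- function(path, idx, coef_floor) {
  b <- path$beta[, idx]
  names(b)[abs(b) >= coef_floor & b != 0]
}

#' Select the four-model family from a cross-validated LASSO path
#'
#' Extracts the predictor supports of the four compared models: `max`
#' (smallest lambda on the grid), `minMSE` (lambda with minimum LOOCV MSE),
#' `oneSE` (largest lambda whose MSE is within one standard error of the
#' minimum) and `min` (largest lambda with exactly one nonzero coefficient).
#' Coefficients with `|value| < coef_floor` are excluded from the supports.
#'
#' @param path a [lasso_path()] that has been through [loocv_mse()].
#' @param coef_floor exclusion threshold on the original-scale coefficients.
#' @return Named list of class `"sop_model_family"` mapping model id to a
#'   list with `predictors` and `lambda`.
#' @export
select_models <- function(path, coef_floor = 1e-3) {
  stopifnot(inherits(path, "lasso_path"))
  if (is.null(path$cv_mse)) stop("run loocv_mse() on the path first")
  if (length(path$lambda) == 0) stop("empty path")
  nz <- colSums(abs(path$beta) >= coef_floor & path$beta != 0)
  if (all(nz == 0))
    stop("all models are empty: coef_floor removed every coefficient")
  i_max <- length(path$lambda)
  i_one <- which(nz == 1)
  if (length(i_one) == 0)
    stop("no lambda on the grid has exactly one nonzero coefficient")
  supports <- list(max = i_max, minMSE = path$i_min, oneSE = path$i_1se,
                   min = i_one[1])
  out <- lapply(names(supports), function(id) {
    idx <- supports[[id]]
    list(model_id = id, predictors = support_at(path, idx, coef_floor),
         lambda = path$lambda[idx])
  })
  names(out) <- names(supports)
  structure(out, class = "sop_model_family", coef_floor = coef_floor)
}

#' Post-selection ordinary least-squares refit
#'
#' Unpenalised linear refit on a selected predictor subset, with standard
#' errors, two-sided t-test p-values, adjusted R^2, and the leave-one-out
#' cross-validated RMSE computed exactly via the hat-matrix identity
#' `e_loo = e / (1 - h)`.
#'
#' @param X full predictor matrix or data frame.
#' @param y response.
#' @param predictors character vector of selected predictor names (may be
#'   empty for the intercept-only model).
#' @param model_id label (`"max"`, `"minMSE"`, `"oneSE"`, `"min"`, ...).
#' @return A list of class `"sop_model"`: `coefficients` (matrix with
#'   estimate, SE, t, p), `predictors`, `loocv_rmse`, `r2`, `r2_adj`, `rss`,
#'   `n`, `fit` (the `lm` object).
#' @export
refit_linear <- function(X, y, predictors, model_id = "model") {
  X <- as_predictor_matrix(X)
  stopifnot(all(predictors %in% colnames(X)))
  if (length(predictors) >= nrow(X) - 2)
    stop("too many predictors for a stable refit (|support| >= n - 2)")
  df <- as.data.frame(X[, predictors, drop = FALSE])
  df$.y <- as.numeric(y)
  fit <- lm(.y ~ ., data = df)
  if (any(is.na(coef(fit)))) stop("rank-deficient refit")
  sm <- summary(fit)
  h <- lm.influence(fit, do.coef = FALSE)$hat
  e_loo <- residuals(fit) / (1 - h)
  structure(list(
    model_id = model_id,
    predictors = predictors,
    coefficients = sm$coefficients,
    loocv_rmse = sqrt(mean(e_loo^2)),
    r2 = sm$r.squared,
    r2_adj = sm$adj.r.squared,
    rss = sum(residuals(fit)^2),
    n = length(y),
    fit = fit), class = "sop_model")
}

#' @importFrom stats lm.influence residuals logLik
gaussian_loglik <- function(rss, n) -n / 2 * (log(2 * pi * rss / n) + 1)

#' Likelihood-ratio and information-criterion comparison of nested models
#'
#' Compares a smaller model nested in a larger one: Gaussian likelihood-ratio
#' statistic with a chi-square reference (df = difference in predictor
#' count), and AIC/BIC differences oriented so that a positive delta supports
#' the larger model (`delta_aic = AIC(smaller) - AIC(larger)`). Support
#' labels: `"moderate"` above 4.6 and `"very strong"` above 13.8 on the
#' delta-AIC scale.
#'
#' @param smaller,larger fitted [refit_linear()] models on the same data;
#'   `smaller$predictors` must be a subset of `larger$predictors`.
#' @return A list of class `"sop_model_comparison"`.
#' @export
compare_models <- function(smaller, larger) {
  stopifnot(inherits(smaller, "sop_model"), inherits(larger, "sop_model"))
  if (!all(smaller$predictors %in% larger$predictors))
    stop("models are not nested")
  if (smaller$n != larger$n) stop("models were fitted on different data")
  n <- smaller$n
  ll_s <- gaussian_loglik(smaller$rss, n)
  ll_b <- gaussian_loglik(larger$rss, n)
  dk <- length(larger$predictors) - length(smaller$predictors)
  lrt <- max(0, 2 * (ll_b - ll_s))
  p <- if (dk > 0) pchisq(lrt, dk, lower.tail = FALSE) else 1
  k_s <- length(smaller$predictors) + 2  # intercept + residual variance
  k_b <- length(larger$predictors) + 2
  aic_s <- -2 * ll_s + 2 * k_s
  aic_b <- -2 * ll_b + 2 * k_b
  bic_s <- -2 * ll_s + log(n) * k_s
  bic_b <- -2 * ll_b + log(n) * k_b
  delta_aic <- aic_s - aic_b
  delta_bic <- bic_s - bic_b
  label <- if (delta_aic > 13.8) "very strong"
  else if (delta_aic > 4.6) "moderate" else "weak"
  structure(list(smaller = smaller$model_id, larger = larger$model_id,
                 lrt_statistic = lrt, lrt_df = dk, lrt_p = p,
                 delta_aic = delta_aic, delta_bic = delta_bic,
                 support_label = label),
            class = "sop_model_comparison")
}

#' @export
print.sop_model_comparison <- function(x, ...) {
  cat(sprintf("%s vs %s: LRT = %.2f (df %d, p = %.3g), dAIC = %.1f, dBIC = %.1f (%s support for the larger model)\n",
              x$smaller, x$larger, x$lrt_statistic, x$lrt_df, x$lrt_p,
              x$delta_aic, x$delta_bic, x$support_label))
  invisible(x)
}
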