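# The main fitting function: LASSO model selection for the postoperative
# standing SOP, returning a classed model-family object.

#' Fit the postoperative standing SOP prediction models
#'
#' Runs the full selection procedure on a preoperative cohort: assembles the
#' scenario's predictor matrix (31 predictors for scenario A, 33 for B),
#' computes the LASSO path with leave-one-out cross-validation, extracts the
#' four-model family (max, minMSE, oneSE, min), refits each model by ordinary
#' least squares, and compares the nested chain min -> oneSE -> minMSE -> max
#' by likelihood-ratio tests and AIC/BIC differences.
#'
#' @param cohort data frame with the predictor columns and the response
#'   `postop_standing_sop` (see [generate_cohort()] and
#'   [predictor_registry()]).
#' @param scenario `"A"` (supine CT only) or `"B"` (supine CT plus standing
#'   imaging).
#' @param config a [study_config()]; supplies the coefficient floor and
#'   significance level.
#' @param nlambda,lambda_min_ratio LASSO grid controls.
#' @return An object of class `"sop_fit"` with components `path` (the
#'   cross-validated [lasso_path()]), `family` (selected supports), `models`
#'   (named list of [refit_linear()] fits), `comparisons` (named list of
#'   [compare_models()] results), `scenario`, `config`.
#' @seealso [coef.sop_fit()], [predict.sop_fit()], [summary.sop_fit()]
#' @export
fit_sop_models <- function(cohort, scenario = c("A", "B"),
                           config = study_config(scenario = scenario),
                           nlambda = 100, lambda_min_ratio = 1e-4) {
  scenario <- match.arg(scenario)
  if (!"postop_standing_sop" %in% names(cohort))
    stop("cohort has no response column 'postop_standing_sop'")
  X <- assemble_predictors(cohort, scenario)
  y <- cohort$postop_standing_sop
  ok <- complete.cases(X) & !is.na(y)
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  path <- lasso_path(X, y, nlambda = nlambda,
                     lambda_min_ratio = lambda_min_ratio)
  path <- loocv_mse(path)
  family <- select_models(path, coef_floor = config$coef_floor)
  models <- lapply(family, function(m)
    refit_linear(X, y, m$predictors, model_id = m$model_id))
  chain <- c("min", "oneSE", "minMSE", "max")
  comparisons <- list()
  for (i in seq_len(length(chain) - 1)) {
    s <- models[[chain[i]]]; b <- models[[chain[i + 1]]]
    nm <- paste(chain[i], "vs", chain[i + 1])
    comparisons[[nm]] <- if (all(s$predictors %in% b$predictors))
      compare_models(s, b) else NULL
  }
  structure(list(path = path, family = family, models = models,
                 comparisons = comparisons, scenario = scenario,
                 config = config),
            class = "sop_fit")
}

#' @export
print.sop_fit <- function(x, ...) {
  cat("postoperative standing SOP model family (scenario", x$scenario, ")\n")
  nop <- vapply(x$models, function(m) length(m$predictors), integer(1))
  rmse <- vapply(x$models, function(m) m$loocv_rmse, numeric(1))
  r2a <- vapply(x$models, function(m) m$r2_adj, numeric(1))
  tab <- data.frame(NoP = nop, RMSE = round(rmse, 2),
                    R2_adj = round(r2a, 3))
  print(tab)
  cat("\noneSE model predictors:",
      paste(x$models$oneSE$predictors, collapse = ", "), "\n")
  invisible(x)
}

#' Summary of a fitted SOP model family
#'
#' @param object an `"sop_fit"`.
#' @param model which model's coefficient table to detail.
#' @param ... unused.
#' @export
summary.sop_fit <- function(object, model = "oneSE", ...) {
  m <- object$models[[model]]
  out <- list(scenario = object$scenario, model = model,
              coefficients = m$coefficients, loocv_rmse = m$loocv_rmse,
              r2_adj = m$r2_adj, n = m$n,
              comparisons = object$comparisons)
  class(out) <- "summary.sop_fit"
  out
}

#' @export
print.summary.sop_fit <- function(x, ...) {
  cat(sprintf("scenario %s, %s model (n = %d)\n", x$scenario, x$model, x$n))
  printCoefmat(x$coefficients, digits = 3)
  cat(sprintf("LOOCV RMSE %.2f deg, adjusted R^2 %.3f\n",
              x$loocv_rmse, x$r2_adj))
  for (cmp in x$comparisons) if (!is.null(cmp)) print(cmp)
  invisible(x)
}

#' @importFrom stats printCoefmat
#' @export
coef.sop_fit <- function(object, model = "oneSE", ...) {
  object$models[[model]]$coefficients[, "Estimate"]
}

#' Predict the postoperative standing SOP
#'
#' @param object an `"sop_fit"`.
#' @param newdata data frame with the predictor columns.
#' @param model which selected model to use.
#' @param ... unused.
#' @return Numeric vector of predicted postoperative standing SOP (degrees).
#' @export
predict.sop_fit <- function(object, newdata, model = "oneSE", ...) {
  m <- object$models[[model]]
  X <- assemble_predictors(newdata, object$scenario)
  df <- as.data.frame(X[, m$predictors, drop = FALSE])
  unname(predict(m$fit, newdata = df))
}

#' @export
residuals.sop_fit <- function(object, model = "oneSE", ...) {
  residuals(object$models[[model]]$fit)
}

#' Plot the cross-validation curve of a fitted SOP model family
#'
#' LOOCV MSE against `log10(lambda)` with one-standard-error bars and the
#' minMSE / oneSE selections marked.
#'
#' @param x an `"sop_fit"`.
#' @param ... passed to [plot()].
#' @export
plot.sop_fit <- function(x, ...) {
  p <- x$path
  ll <- log10(p$lambda)
  plot(ll, p$cv_mse, type = "l", xlab = expression(log[10](lambda)),
       ylab = "LOOCV MSE (deg^2)", ...)
  lines(ll, p$cv_mse + p$cv_se, lty = 3)
  lines(ll, p$cv_mse - p$cv_se, lty = 3)
  abline(v = ll[p$i_min], col = 2, lty = 2)
  abline(v = ll[p$i_1se], col = 4, lty = 2)
  legend("topleft", legend = c("minMSE", "oneSE"), col = c(2, 4), lty = 2,
         bty = "n")
  invisible(x)
}

#' Export the model-family tables
#'
#' Writes the family comparison (number of predictors, LOOCV RMSE, adjusted
#' R^2, delta-AIC/BIC, LRT p) and the per-model coefficient tables.
#'
#' @param fit an `"sop_fit"`.
#' @param path_comparison,path_coefficients output CSV paths (either may be
#'   `NULL` to skip).
#' @return Invisibly, the comparison data frame.
#' @export
write_model_report <- function(fit, path_comparison = NULL,
                               path_coefficients = NULL) {
  chain <- c("max", "minMSE", "oneSE", "min")
  rows <- lapply(chain, function(id) {
    m <- fit$models[[id]]
    data.frame(model = id, NoP = length(m$predictors),
               RMSE = m$loocv_rmse, R2_adj = m$r2_adj)
  })
  tab <- do.call(rbind, rows)
  cmp_names <- names(fit$comparisons)
  tab$delta_aic <- tab$delta_bic <- tab$lrt_p <- NA_real_
  for (nm in cmp_names) {
    cmp <- fit$comparisons[[nm]]
    if (is.null(cmp)) next
    i <- match(cmp$larger, tab$model)
    tab$delta_aic[i] <- cmp$delta_aic
    tab$delta_bic[i] <- cmp$delta_bic
    tab$lrt_p[i] <- cmp$lrt_p
  }
  if (!is.null(path_comparison))
    write.csv(tab, path_comparison, row.names = FALSE)
  if (!is.null(path_coefficients)) {
    ct <- do.call(rbind, lapply(chain, function(id) {
      cc <- fit$models[[id]]$coefficients
      data.frame(model = id, parameter = rownames(cc),
                 estimate = cc[, "Estimate"], se = cc[, "Std. Error"],
                 p = cc[, "Pr(>|t|)"], row.names = NULL)
    }))
    write.csv(ct, path_coefficients, row.names = FALSE)
  }
  invisible(tab)
}
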