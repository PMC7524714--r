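test_that("the penalised path has the expected endpoints", {
  toy <- make_toy_regression()
  fit <- lasso_path(toy$X, toy$y, lambda = c(1e6, 0))
  expect_true(all(fit$beta[, 1] == 0))           # above lambda_max
  # lambda = 0 equals the normal-equations OLS oracle
  ols <- solve(crossprod(cbind(1, toy$X)), crossprod(cbind(1, toy$X), toy$y))
  expect_equal(unname(fit$beta[, 2]), unname(ols[-1]), tolerance = 1e-6)
  expect_equal(fit$intercept[2], ols[1], tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("orthonormal designs soft-threshold exactly", {
  set.seed(33)
  n <- 80
  raw <- scale(matrix(rnorm(n * 4), n, 4), center = TRUE, scale = FALSE)
  Z <- sqrt(n) * qr.Q(qr(raw))  # centred, population SD 1, Z'Z/n = I
  colnames(Z) <- paste0("z", 1:4)
  y <- 2 + Z %*% c(1.5, -0.8, 0.3, 0) + rnorm(n, 0, 0.5)
  lam <- c(0.6, 0.25, 0.05)
  fit <- lasso_path(Z, y, lambda = lam)
  bols <- crossprod(Z, y - mean(y)) / n
  soft <- function(b, l) sign(b) * pmax(abs(b) - l, 0)
  for (j in seq_along(lam))
    expect_equal(unname(fit$beta[, j]), unname(soft(bols, lam[j])[, 1]),
                 tolerance = 1e-7)
})

test_that("the path matches glmnet on a random design", {
  toy <- make_toy_regression(n = 150, p = 8, seed = 7)
  lam <- c(0.8, 0.3, 0.1, 0.02)
  fit <- lasso_path(toy$X, toy$y, lambda = lam)
  g <- glmnet::glmnet(toy$X, toy$y, lambda = lam, standardize = TRUE,
                      thresh = 1e-12)
  expect_equal(unname(fit$beta), unname(as.matrix(g$beta)), tolerance = 1e-5)
  expect_equal(fit$intercept, unname(g$a0), tolerance = 1e-5)
})

test_that("constant predictors are dropped with a warning", {
  toy <- make_toy_regression()
  X <- cbind(toy$X, flat = 1)
  expect_warning(fit <- lasso_path(X, toy$y, lambda = c(0.5, 0.1)),
                 "constant predictor")
  expect_true(all(fit$beta["flat", ] == 0))
})

test_that("LOOCV at lambda = 0 equals the hat-matrix identity", {
  toy <- make_toy_regression(n = 20, p = 3, seed = 12)
  path <- lasso_path(toy$X, toy$y, lambda = c(1, 0))
  path <- loocv_mse(path)
  fit <- lm(toy$y ~ toy$X)
  h <- lm.influence(fit, do.coef = FALSE)$hat
  oracle <- mean((residuals(fit) / (1 - h))^2)
  expect_equal(path$cv_mse[2], oracle, tolerance = 1e-4)
})

test_that("LOOCV error vanishes for a noiseless single-predictor model", {
  set.seed(2)
  X <- cbind(a = rnorm(40))
  y <- 3 + 2 * X[, 1]
  path <- loocv_mse(lasso_path(X, y))
  expect_lt(min(path$cv_mse), 1e-4)
})

test_that("a permuted response yields a null-level minimum MSE", {
  set.seed(15)
  toy <- make_toy_regression(n = 100, p = 5, seed = 15)
  y_perm <- sample(toy$y)
  path <- loocv_mse(lasso_path(toy$X, y_perm))
  vy <- var(y_perm)
  expect_lt(abs(min(path$cv_mse) - vy) / vy, 0.2)
})

test_that("the four-model family is extracted per definition", {
  set.seed(18)
  X <- cbind(signal = rnorm(120), junk1 = rnorm(120), junk2 = rnorm(120))
  y <- 2 + 3 * X[, "signal"] + rnorm(120, 0, 0.5)
  path <- loocv_mse(lasso_path(X, y))
  fam <- select_models(path)
  for (id in names(fam)) expect_true("signal" %in% fam[[id]]$predictors)
  expect_length(fam$min$predictors, 1)
  # the oneSE lambda obeys its defining inequality
  thresh <- path$cv_mse[path$i_min] + path$cv_se[path$i_min]
  expect_lte(path$cv_mse[path$i_1se], thresh)
  expect_gte(fam$oneSE$lambda, fam$minMSE$lambda)
  # model sizes are ordered min <= oneSE <= minMSE <= max
  sizes <- vapply(fam[c("min", "oneSE", "minMSE", "max")],
                  function(m) length(m$predictors), integer(1))
  expect_true(all(diff(sizes) >= 0))
  expect_error(select_models(path, coef_floor = Inf), "empty")
})

test_that("post-selection refits recover an orthogonal design exactly", {
  set.seed(25)
  n <- 64
  Z <- sqrt(n) * qr.Q(qr(scale(matrix(rnorm(n * 3), n, 3), scale = FALSE)))
  colnames(Z) <- c("a", "b", "c")
  beta <- c(2, -1, 0.5)
  y <- 1 + as.numeric(Z %*% beta)  # no noise: exact recovery
  m <- suppressWarnings(refit_linear(Z, y, c("a", "b", "c")))  # perfect fit
  expect_equal(unname(m$coefficients[-1, "Estimate"]), beta, tolerance = 1e-9)
  expect_lte(m$r2_adj, m$r2)
  dup <- cbind(Z, a2 = Z[, "a"])
  expect_error(refit_linear(dup, y, c("a", "a2", "b")), "rank-deficient")
})

test_that("nested-model comparison matches the closed form", {
  toy <- make_toy_regression(n = 10, p = 3, seed = 3)
  m1 <- refit_linear(toy$X, toy$y, "v1", "small")
  cmp_same <- compare_models(m1, m1)
  expect_equal(cmp_same$lrt_statistic, 0)
  expect_equal(cmp_same$lrt_df, 0)
  expect_equal(cmp_same$delta_aic, 0)
  # hand-computed toy: RSS 20 vs 10, n = 10, one extra parameter
  small <- structure(list(model_id = "s", predictors = "v1", rss = 20,
                          n = 10), class = "sop_model")
  big <- structure(list(model_id = "b", predictors = c("v1", "v2"), rss = 10,
                        n = 10), class = "sop_model")
  cmp <- compare_models(small, big)
  expect_equal(cmp$lrt_statistic, 10 * log(2), tolerance = 1e-12)
  expect_equal(cmp$lrt_df, 1)
  expect_equal(cmp$delta_aic, 10 * log(2) - 2, tolerance = 1e-12)
  expect_error(compare_models(big, small), "not nested")
})

test_that("the LRT null distribution is chi-square with one degree of freedom", {
  set.seed(77)
  stats <- replicate(400, {
    n <- 40
    x1 <- rnorm(n); noise <- rnorm(n)
    y <- 1 + 0.8 * x1 + rnorm(n)
    X <- cbind(x1 = x1, noise = noise)
    small <- refit_linear(X, y, "x1", "small")
    big <- refit_linear(X, y, c("x1", "noise"), "big")
    compare_models(small, big)$lrt_statistic
  })
  ks <- suppressWarnings(stats::ks.test(stats, "pchisq", df = 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("fit_sop_models returns a coherent model family on a cohort", {
  coh <- generate_cohort(generator_config(300, "A", seed = 30))
  fit <- fit_sop_models(coh, "A")
  expect_s3_class(fit, "sop_fit")
  expect_named(fit$models, c("max", "minMSE", "oneSE", "min"))
  for (m in fit$models) expect_true("supine_sop" %in% m$predictors)
  # coefficient access and prediction
  cf <- coef(fit, "oneSE")
  expect_true("(Intercept)" %in% names(cf))
  pred <- predict(fit, coh, model = "oneSE")
  expect_length(pred, nrow(coh))
  expect_gt(cor(pred, coh$postop_standing_sop), 0.7)
  # printed output mentions the oneSE model
  expect_output(print(fit), "oneSE")
  expect_output(print(summary(fit)), "LOOCV RMSE")
})
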