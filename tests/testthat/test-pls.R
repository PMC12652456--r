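test_that("SIMPLS predictions match an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  X <- withr::with_seed(1, matrix(rnorm(100 * 20), 100))
  colnames(X) <- paste0("V", 1:20)
  y <- withr::with_seed(2, as.vector(X %*% rnorm(20) + rnorm(100, 0, 0.1)))
  fit <- tanninfuse:::simpls_fit(X, y, 5)
  ref <- mixOmics::pls(X, as.matrix(y), ncomp = 5, mode = "regression",
                       scale = FALSE)
  ref_pred <- predict(ref, X)$predict[, 1, ]
  for (k in 1:5) {
    expect_equal(tanninfuse:::simpls_predict(fit, X, k),
                 unname(ref_pred[, k]), tolerance = 1e-10)
  }
})

test_that("PLS recovers exact linear structure and the OLS limit", {
  X <- withr::with_seed(3, matrix(rnorm(60 * 8), 60))
  y <- 3 * X[, 1]
  m <- fit_pls(X, y, stratified_kfold(y, seed = 1))
  expect_gt(r_squared(y, predict(m, X)), 1 - 1e-8)

  # at full rank the PLS fit matches ordinary least squares
  yn <- withr::with_seed(4, as.vector(X %*% rnorm(8) + rnorm(60)))
  full <- tanninfuse:::simpls_fit(X, yn, 8)
  ols <- lm.fit(cbind(1, X), yn)
  pls_res <- yn - tanninfuse:::simpls_predict(full, X, full$ncomp)
  expect_equal(pls_res, unname(ols$residuals), tolerance = 1e-8)
})

test_that("PLS is invariant to feature permutation", {
  X <- withr::with_seed(5, matrix(rnorm(50 * 10), 50))
  y <- withr::with_seed(6, as.vector(X %*% rnorm(10) + rnorm(50, 0, 0.2)))
  perm <- withr::with_seed(7, sample(10))
  m1 <- fit_pls(X, y, max_components = 4)
  m2 <- fit_pls(X[, perm], y, max_components = 4)
  expect_equal(predict(m1, X), predict(m2, X[, perm]), tolerance = 1e-10)
})

test_that("RMSECV matches its definition and null behavior", {
  # noise-free linear response: essentially zero CV error
  X <- withr::with_seed(8, matrix(rnorm(60 * 5), 60))
  y <- as.vector(X %*% c(1, -2, 0.5, 3, -1))
  folds <- stratified_kfold(y, seed = 2)
  expect_lt(rmsecv(X, y, folds, 5), 1e-8)

  # equals a brute-force loop over folds
  yn <- withr::with_seed(9, y + rnorm(60, 0, 0.5))
  got <- rmsecv(X, yn, folds, 3)
  press <- numeric(60)
  for (f in folds$folds) {
    fit <- tanninfuse:::simpls_fit(X[-f, ], yn[-f], 3)
    press[f] <- tanninfuse:::simpls_predict(fit, X[f, , drop = FALSE], 3) - yn[f]
  }
  expect_equal(got, sqrt(mean(press^2)), tolerance = 1e-12)

  # y independent of X: RMSECV stays near sd(y)
  Xn <- withr::with_seed(10, matrix(rnorm(400 * 20), 400))
  y0 <- withr::with_seed(11, rnorm(400))
  expect_lt(abs(rmsecv(Xn, y0, stratified_kfold(y0, seed = 3), 2) / sd(y0) - 1),
            0.15)

  expect_error(rmsecv(X, y, folds, 50), "infeasible")
})
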