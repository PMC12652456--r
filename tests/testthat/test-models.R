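test_that("SVR tuning finds a strong model on linear data", {
  X <- withr::with_seed(1, matrix(rnorm(200 * 6), 200))
  beta <- c(2, -1, 0.5, 1, 0, 0)
  y <- withr::with_seed(2, as.vector(X %*% beta + rnorm(200, 0, sd(X %*% beta) / 10)))
  folds <- stratified_kfold(y, seed = 1)
  m <- tune_fit_svr(X, y, folds = folds)
  expect_gte(m$cv_r2, 0.9)
  expect_equal(nrow(m$search), 30)
})

test_that("SVR ties resolve to the smaller C then smaller gamma", {
  X <- withr::with_seed(3, matrix(rnorm(80 * 4), 80))
  y <- withr::with_seed(4, as.vector(X %*% c(1, 1, 0, 0) + rnorm(80, 0, 0.2)))
  folds <- stratified_kfold(y, seed = 2)
  m1 <- tune_fit_svr(X, y, folds = folds)
  # appending a duplicate of the winning pair must not change the winner
  spec2 <- svr_spec(C = c(c(0.1, 1, 10, 100, 1000), m1$C),
                    gamma = c(0.0001, 0.001, 0.01, 0.1, 1, 10))
  m2 <- tune_fit_svr(X, y, spec2, folds = folds)
  expect_equal(c(m2$C, m2$gamma), c(m1$C, m1$gamma))
  expect_error(tune_fit_svr(X, rep(1, 80), folds = folds), "constant")
})

test_that("a conv-free CNN degenerates to a linear model", {
  X <- withr::with_seed(5, matrix(rnorm(80 * 10), 80))
  y <- as.vector(X %*% c(2, -1, rep(0, 8))) + 1
  m <- fit_cnn(X, y, cnn_spec(conv_blocks = list(), dense_width = 0,
                              learning_rate = 0.05, max_epochs = 400), seed = 3)
  expect_gte(r_squared(y, predict(m, X)), 0.99)
})

test_that("CNN gradients match finite differences", {
  X <- withr::with_seed(6, matrix(rnorm(8 * 12), 8))
  y <- withr::with_seed(7, rnorm(8))
  spec <- cnn_spec(conv_blocks = list(list(filters = 2, kernel = 3, pool = 2)),
                   dense_width = 4, dropout = 0, l2 = 0)
  net <- withr::with_seed(8, tanninfuse:::cnn_build(spec, 12))
  lg <- withr::with_seed(9, tanninfuse:::cnn_loss_grad(net, X, y, 0))
  eps <- 1e-6
  for (li in seq_along(net$layers)) {
    W <- net$layers[[li]]$W
    if (is.null(W)) next
    for (idx in c(1, length(W))) {
      net_p <- net; net_p$layers[[li]]$W[idx] <- W[idx] + eps
      net_m <- net; net_m$layers[[li]]$W[idx] <- W[idx] - eps
      num <- (tanninfuse:::cnn_eval_loss(net_p, X, y) -
                tanninfuse:::cnn_eval_loss(net_m, X, y)) / (2 * eps)
      expect_equal(lg$grads[[li]]$W[idx], num, tolerance = 1e-4)
    }
  }
})

test_that("CNN training is seeded, improving, and stops on schedule", {
  ss <- small_sample_set(n = 70, seed = 10)
  X <- spectra_matrix(ss$vnir); y <- ss$reference$tannin
  spec <- cnn_spec(max_epochs = 120)
  m1 <- fit_cnn(X, y, spec, seed = 4)
  m2 <- fit_cnn(X, y, spec, seed = 4)
  expect_identical(predict(m1, X), predict(m2, X))
  # smoothed training loss decreases over the first 10 epochs
  h <- m1$history$train_loss
  sm <- stats::filter(h, rep(1 / 3, 3), sides = 1)
  expect_lt(sm[10], sm[3])
  # early stopping halts within patience epochs of the best validation loss
  expect_lte(m1$stopped_epoch - m1$best_epoch, spec$patience)
})

test_that("prediction is deterministic, batch-consistent, width-checked", {
  ss <- small_sample_set(n = 40, seed = 12)
  X <- spectra_matrix(ss$swir); y <- ss$reference$tannin
  folds <- stratified_kfold(y, seed = 5)
  models <- list(fit_pls(X, y, folds),
                 tune_fit_svr(X, y, folds = folds),
                 fit_cnn(X, y, cnn_spec(max_epochs = 40), seed = 6))
  for (m in models) {
    p1 <- predict(m, X)
    expect_identical(p1, predict(m, X))
    expect_true(all(is.finite(p1)))
    loop <- vapply(seq_len(nrow(X)), function(i) {
      predict(m, X[i, , drop = FALSE])
    }, numeric(1))
    expect_equal(p1, loop, tolerance = 1e-10)
    expect_error(predict(m, X[, -1, drop = FALSE]), "features")
  }
  # an interpolating PLS reproduces its training responses
  Xs <- X[1:12, 1:20]; ys <- y[1:12]
  interp <- fit_pls(Xs, ys, max_components = 11)
  expect_equal(predict(interp, Xs), ys, tolerance = 1e-6)
})

test_that("nonlinear families capture structure PLS cannot", {
  # response nonlinear in the latent factor: kernel methods must clearly win
  withr::with_seed(13, {
    n <- 150
    f <- runif(n, -2, 2)
    X <- outer(f, seq(-1, 1, length.out = 20)) +
      matrix(rnorm(n * 20, 0, 0.05), n)
    y <- f^2 + rnorm(n, 0, 0.1)
  })
  folds <- stratified_kfold(y, seed = 7)
  r2_pls <- r_squared(y, predict(fit_pls(X, y, folds), X))
  m_svr <- tune_fit_svr(X, y, folds = folds)
  expect_gt(m_svr$cv_r2, 0.8)
  expect_gt(m_svr$cv_r2, r2_pls + 0.3)
})

test_that("tidy and glance expose fit summaries", {
  ss <- small_sample_set(n = 30, seed = 14)
  X <- spectra_matrix(ss$swir); y <- ss$reference$tannin
  m <- fit_pls(X, y, stratified_kfold(y, seed = 8))
  td <- tidy(m)
  expect_equal(nrow(td), ncol(X))
  gl <- glance(m)
  expect_identical(gl$family, "pls")
  ms <- tune_fit_svr(X, y, folds = stratified_kfold(y, seed = 8))
  expect_true(all(c("C", "gamma", "cv_r2") %in% names(tidy(ms))))
})
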