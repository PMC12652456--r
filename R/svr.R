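#' SVR hyperparameter grid
#'
#' The RBF support-vector-regression search space: every combination of
#' `C` in \{0.1, 1, 10, 100, 1000\} and `gamma` in \{0.0001, 0.001, 0.01,
#' 0.1, 1, 10\} (30 pairs), with a fixed epsilon-tube width.
#'
#' @param C,gamma Numeric grids.
#' @param epsilon Epsilon-insensitive tube width (default 0.1).
#' @return An `svr_spec` list.
#' @export
svr_spec <- function(C = c(0.1, 1, 10, 100, 1000),
                     gamma = c(0.0001, 0.001, 0.01, 0.1, 1, 10),
                     epsilon = 0.1) {
  assert_that_(length(C) >= 1 && all(C > 0), "`C` grid must be positive.")
  assert_that_(length(gamma) >= 1 && all(gamma > 0), "`gamma` grid must be positive.")
  structure(list(C = C, gamma = gamma, epsilon = epsilon), class = "svr_spec")
}

#' Tune and fit an RBF support-vector regression
#'
#' Exhaustive search over the (C, gamma) grid. Each pair is scored by the
#' mean per-fold prediction R-squared over the supplied cross-validation
#' folds; the winner (ties broken toward smaller C, then smaller gamma) is
#' refit on all calibration rows. Features are standardized with
#' calibration-set mean/SD inside the wrapper, so fused blocks stay raw at
#' the fusion stage.
#'
#' @param X Predictor matrix or [spectra_tbl()].
#' @param y Numeric response (must not be constant).
#' @param spec An [svr_spec()].
#' @param folds [stratified_kfold()] folds over the rows of `X`.
#' @return A `tannin_model` of family `"svr"`; `$search` holds the full grid
#'   with per-pair CV scores.
#' @export
tune_fit_svr <- function(X, y, spec = svr_spec(), folds = NULL) {
  if (inherits(X, "spectra_tbl")) X <- spectra_matrix(X)
  X <- as.matrix(X)
  assert_that_(stats::var(y) > 0, "`y` is constant; SVR tuning is undefined.")
  if (is.null(folds)) folds <- stratified_kfold(y, seed = 0L)
  fold_list <- if (inherits(folds, "cv_folds")) folds$folds else folds
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[scale < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, center, "-"), 2, scale, "/")
  grid <- expand.grid(gamma = spec$gamma, C = spec$C,
                      KEEP.OUT.ATTRS = FALSE)[, c("C", "gamma")]
  score_pair <- function(C, gamma) {
    r2 <- vapply(fold_list, function(f) {
      fit <- e1071::svm(Xs[-f, , drop = FALSE], y[-f], type = "eps-regression",
                        kernel = "radial", cost = C, gamma = gamma,
                        epsilon = spec$epsilon, scale = FALSE)
      pred <- predict(fit, Xs[f, , drop = FALSE])
      if (stats::var(y[f]) == 0) return(NA_real_)
      1 - sum((pred - y[f])^2) / sum((y[f] - mean(y[f]))^2)
    }, numeric(1))
    mean(r2, na.rm = TRUE)
  }
  scores <- purrr::map2_dbl(grid$C, grid$gamma, score_pair)
  # ties toward smaller C then smaller gamma: order candidates accordingly
  ord <- order(-scores, grid$C, grid$gamma)
  best <- ord[1]
  fit <- e1071::svm(Xs, y, type = "eps-regression", kernel = "radial",
                    cost = grid$C[best], gamma = grid$gamma[best],
                    epsilon = spec$epsilon, scale = FALSE)
  new_tannin_model("svr",
                   fit = fit, C = grid$C[best], gamma = grid$gamma[best],
                   epsilon = spec$epsilon, cv_r2 = scores[best],
                   search = tibble::tibble(C = grid$C, gamma = grid$gamma,
                                           cv_r2 = scores),
                   center = center, scale = scale,
                   feature_width = ncol(X))
}
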