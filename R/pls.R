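# SIMPLS (de Jong 1993) for a univariate response. Returns coefficient paths
# for 1..ncomp components so cross-validation over the component count costs a
# single fit. X is centred internally; y is centred; no scaling (raw spectra
# are modelled as-is, matching the study protocol).
simpls_fit <- function(X, y, ncomp) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  assert_that_(length(y) == n, "X row count must match length(y).")
  ncomp <- min(ncomp, n - 1L, p)
  assert_that_(ncomp >= 1, "no PLS component is estimable (rank below 1).")
  mx <- colMeans(X); my <- mean(y)
  Xc <- sweep(X, 2, mx, "-"); yc <- y - my
  R <- matrix(0, p, ncomp)   # weights (X scores TT = Xc %*% R)
  Q <- numeric(ncomp)        # y loadings
  V <- matrix(0, p, ncomp)   # orthonormal basis of X loadings
  S <- crossprod(Xc, yc)     # p x 1 cross-covariance
  a_used <- 0L
  for (a in seq_len(ncomp)) {
    r <- S
    t_a <- Xc %*% r
    nt <- sqrt(sum(t_a^2))
    if (!is.finite(nt) || nt < 1e-12) break
    t_a <- t_a / nt
    r <- r / nt
    p_a <- crossprod(Xc, t_a)
    q_a <- sum(yc * t_a)
    v <- p_a
    if (a > 1) {
      vv <- V[, seq_len(a - 1L), drop = FALSE]
      v <- v - vv %*% crossprod(vv, p_a)
    }
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) break
    v <- v / nv
    S <- S - v %*% crossprod(v, S)
    R[, a] <- r; Q[a] <- q_a; V[, a] <- v
    a_used <- a
  }
  assert_that_(a_used >= 1, "PLS deflation collapsed before one component.")
  # coefficient path: B[, k] are the regression coefficients using k components
  B <- sapply(seq_len(a_used), function(k) {
    R[, seq_len(k), drop = FALSE] %*% Q[seq_len(k)]
  })
  B <- matrix(B, nrow = p)
  intercepts <- my - as.vector(crossprod(mx, B))
  list(coefficients = B, intercepts = intercepts,
       ncomp = a_used, x_means = mx, y_mean = my)
}

simpls_predict <- function(fit, X, ncomp = fit$ncomp) {
  ncomp <- min(ncomp, fit$ncomp)
  as.vector(as.matrix(X) %*% fit$coefficients[, ncomp] + fit$intercepts[ncomp])
}

# Pooled cross-validated RMSE of PLS predictions for each component count
# 1..max_components: fits on each fold's complement, predicts the held-out
# fold, pools all held-out residuals (the CV analogue of the plain RMSE
# definition), and returns the per-component RMSE vector.
rmsecv_path <- function(X, y, folds, max_components) {
  X <- as.matrix(X)
  n <- nrow(X)
  fold_list <- if (inherits(folds, "cv_folds")) folds$folds else folds
  max_fold <- max(lengths(fold_list))
  kmax <- min(max_components, n - max_fold - 1L, ncol(X))
  assert_that_(kmax >= 1,
               "component count infeasible for the fold sizes provided.")
  press <- matrix(NA_real_, n, kmax)
  for (f in fold_list) {
    fit <- simpls_fit(X[-f, , drop = FALSE], y[-f], kmax)
    for (k in seq_len(fit$ncomp)) {
      press[f, k] <- simpls_predict(fit, X[f, , drop = FALSE], k) - y[f]
    }
    if (fit$ncomp < kmax) { # rank collapsed on this fold: reuse last path
      for (k in seq(fit$ncomp + 1L, kmax)) press[f, k] <- press[f, fit$ncomp]
    }
  }
  sqrt(colMeans(press^2))
}

#' Cross-validated RMSE of a PLS model
#'
#' Root-mean-squared error of fold-held-out PLS predictions pooled over all
#' samples — the screening statistic CARS uses to rank wavelength subsets.
#'
#' @param X Predictor matrix (samples x bands).
#' @param y Numeric response.
#' @param folds A [stratified_kfold()] result or list of fold index vectors.
#' @param n_components Number of latent variables (must be feasible for the
#'   fold sizes).
#' @return The pooled RMSECV (single number).
#' @export
rmsecv <- function(X, y, folds, n_components) {
  path <- rmsecv_path(X, y, folds, n_components)
  assert_that_(length(path) >= n_components,
               "component count infeasible for the fold sizes provided.")
  path[n_components]
}

#' Fit a PLS calibration model
#'
#' Partial least squares with the component count chosen to minimize the
#' pooled cross-validated RMSE over the supplied folds (ties go to the
#' smaller count). Predictors are centred, not scaled.
#'
#' @param X Predictor matrix (samples x bands) or [spectra_tbl()].
#' @param y Numeric response (tannin %).
#' @param folds [stratified_kfold()] folds over the rows of `X`; `NULL` fits
#'   with `max_components` directly.
#' @param max_components Upper bound on the latent-variable count (default 10).
#' @return A `tannin_model` of family `"pls"` with elements `fit`, `ncomp`,
#'   `rmsecv_path`, `feature_width`.
#' @examples
#' X <- matrix(rnorm(300), 50); y <- X[, 1] * 3
#' m <- fit_pls(X, y, stratified_kfold(y, seed = 1))
#' cor(predict(m, X), y)
#' @export
fit_pls <- function(X, y, folds = NULL, max_components = 10) {
  if (inherits(X, "spectra_tbl")) X <- spectra_matrix(X)
  X <- as.matrix(X)
  path <- NULL
  if (is.null(folds)) {
    ncomp <- min(max_components, nrow(X) - 1L, ncol(X))
  } else {
    path <- rmsecv_path(X, y, folds, max_components)
    ncomp <- which.min(path)  # which.min takes the first (smallest) minimizer
  }
  fit <- simpls_fit(X, y, ncomp)
  new_tannin_model("pls",
                   fit = fit, ncomp = fit$ncomp, rmsecv_path = path,
                   feature_width = ncol(X))
}
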