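new_tannin_model <- function(family, ...) {
  structure(list(family = family, ...),
            class = c(paste0("tannin_", family), "tannin_model"))
}

#' @export
print.tannin_model <- function(x, ...) {
  extra <- switch(x$family,
                  pls = sprintf("%d components", x$ncomp),
                  svr = sprintf("C = %g, gamma = %g, epsilon = %g",
                                x$C, x$gamma, x$epsilon),
                  cnn = sprintf("stopped at epoch %d", x$stopped_epoch),
                  "")
  cat(sprintf("<tannin_model [%s]: %d features; %s>\n",
              toupper(x$family), x$feature_width, extra))
  invisible(x)
}

check_predict_width <- function(model, X) {
  assert_that_(ncol(X) == model$feature_width,
               sprintf("model was trained on %d features but received %d.",
                       model$feature_width, ncol(X)))
}

#' Predict tannin content from a fitted model
#'
#' Deterministic at inference for all families; the feature width must match
#' the training width.
#'
#' @param object A `tannin_model` from [fit_pls()], [tune_fit_svr()] or
#'   [fit_cnn()].
#' @param newdata Matrix or [spectra_tbl()] with the training feature width.
#' @param ... Unused.
#' @return Numeric vector of predicted tannin contents (%).
#' @export
predict.tannin_pls <- function(object, newdata, ...) {
  if (inherits(newdata, "spectra_tbl")) newdata <- spectra_matrix(newdata)
  newdata <- as.matrix(newdata)
  check_predict_width(object, newdata)
  simpls_predict(object$fit, newdata, object$ncomp)
}

#' @rdname predict.tannin_pls
#' @export
predict.tannin_svr <- function(object, newdata, ...) {
  if (inherits(newdata, "spectra_tbl")) newdata <- spectra_matrix(newdata)
  newdata <- as.matrix(newdata)
  check_predict_width(object, newdata)
  Xs <- sweep(sweep(newdata, 2, object$center, "-"), 2, object$scale, "/")
  unname(predict(object$fit, Xs))
}

#' @rdname predict.tannin_pls
#' @export
predict.tannin_cnn <- function(object, newdata, ...) {
  if (inherits(newdata, "spectra_tbl")) newdata <- spectra_matrix(newdata)
  newdata <- as.matrix(newdata)
  check_predict_width(object, newdata)
  Xs <- sweep(sweep(newdata, 2, object$center, "-"), 2, object$scale, "/")
  as.vector(cnn_forward(object$net, Xs, training = FALSE)$yhat) *
    object$y_scale + object$y_center
}

#' Tidy a fitted tannin model
#'
#' `tidy()` returns per-term information: PLS regression coefficients per
#' band, the SVR hyperparameter grid search results, or the CNN layer sizes.
#' `glance()` returns a one-row fit summary.
#'
#' @param x A `tannin_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.tannin_model <- function(x, ...) {
  switch(x$family,
         pls = tibble::tibble(
           term = paste0("band_", seq_len(x$feature_width)),
           estimate = as.vector(x$fit$coefficients[, x$ncomp])),
         svr = x$search,
         cnn = tibble::tibble(
           term = vapply(x$net$layers, function(l) l$type, character(1)),
           parameters = vapply(x$net$layers, cnn_layer_params, numeric(1))),
         abort("unknown model family."))
}

#' @rdname tidy.tannin_model
#' @export
glance.tannin_model <- function(x, ...) {
  base <- tibble::tibble(family = x$family, n_features = x$feature_width)
  extra <- switch(x$family,
                  pls = tibble::tibble(n_components = x$ncomp),
                  svr = tibble::tibble(C = x$C, gamma = x$gamma,
                                       epsilon = x$epsilon,
                                       cv_r2 = x$cv_r2),
                  cnn = tibble::tibble(stopped_epoch = x$stopped_epoch,
                                       best_val_loss = x$best_val_loss),
                  tibble::tibble())
  dplyr::bind_cols(base, extra)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
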