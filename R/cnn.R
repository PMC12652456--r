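#' CNN specification
#'
#' Architecture and training protocol of the 1-D convolutional regression
#' network: stacked conv blocks (ReLU activation, max pooling), a dense ReLU
#' layer with dropout, and a linear output head. Training uses Adam with a
#' step-decay learning-rate schedule, L2 weight regularization, and early
#' stopping on a held-out validation fraction of the calibration set.
#'
#' @param conv_blocks List of blocks, each `list(filters =, kernel =, pool =)`.
#'   The default is two blocks (16 and 32 filters, kernel 5, pool 2). An empty
#'   list together with `dense_width = 0` degenerates to a linear model.
#' @param dense_width Width of the dense ReLU layer (0 to skip it).
#' @param learning_rate Initial Adam learning rate (default 1e-3, which
#'   reaches a validation-loss plateau within the early-stopping patience at
#'   calibration sizes around 180 samples; smaller rates underfit before the
#'   stopping rule triggers).
#' @param lr_drop_period Epoch period of the step decay (default 600).
#' @param lr_drop_factor Multiplicative decay factor at each period
#'   (default 0.1).
#' @param dropout Dropout rate in the dense layer (default 0.5).
#' @param l2 L2 weight-regularization coefficient (default 1e-5).
#' @param patience Early-stopping patience in epochs (default 20).
#' @param min_delta Minimum validation-loss improvement counted as progress
#'   (default 0.001).
#' @param max_epochs Training epoch cap (default 500).
#' @param batch_size Mini-batch size (default 32).
#' @param validation_fraction Fraction of calibration rows held out for the
#'   early-stopping monitor (default 0.2).
#' @param seed Seed for initialization, shuffling and dropout.
#' @return A `cnn_spec` list.
#' @export
cnn_spec <- function(conv_blocks = list(list(filters = 16, kernel = 5, pool = 2),
                                        list(filters = 32, kernel = 5, pool = 2)),
                     dense_width = 64,
                     learning_rate = 1e-3,
                     lr_drop_period = 600,
                     lr_drop_factor = 0.1,
                     dropout = 0.5,
                     l2 = 1e-5,
                     patience = 20,
                     min_delta = 0.001,
                     max_epochs = 500,
                     batch_size = 32,
                     validation_fraction = 0.2,
                     seed = NULL) {
  assert_that_(dropout >= 0 && dropout < 1, "`dropout` must be in [0, 1).")
  assert_that_(learning_rate > 0 && l2 >= 0 && lr_drop_factor > 0,
               "rates must be positive.")
  assert_that_(validation_fraction > 0 && validation_fraction < 1,
               "`validation_fraction` must be in (0, 1).")
  structure(list(conv_blocks = conv_blocks, dense_width = dense_width,
                 learning_rate = learning_rate,
                 lr_drop_period = lr_drop_period,
                 lr_drop_factor = lr_drop_factor,
                 dropout = dropout, l2 = l2, patience = patience,
                 min_delta = min_delta, max_epochs = max_epochs,
                 batch_size = batch_size,
                 validation_fraction = validation_fraction, seed = seed),
            class = "cnn_spec")
}

# ---- network construction ---------------------------------------------------

cnn_build <- function(spec, p) {
  layers <- list()
  L <- p; C <- 1L
  skipped <- 0L
  for (blk in spec$conv_blocks) {
    k <- blk$kernel
    if (L < k) { # input narrower than the kernel: skip the block (tiny
      skipped <- skipped + 1L # CARS subsets are legitimate inputs)
      next
    }
    fan_in <- k * C
    layers[[length(layers) + 1]] <- list(
      type = "conv", kernel = k, in_ch = C, filters = blk$filters,
      W = matrix(stats::rnorm(fan_in * blk$filters, 0, sqrt(2 / fan_in)),
                 fan_in, blk$filters),
      b = numeric(blk$filters))
    L <- L - k + 1L; C <- blk$filters
    pool <- blk$pool %||% 1
    if (pool > 1 && L >= 2 * pool) {
      layers[[length(layers) + 1]] <- list(type = "pool", width = pool)
      L <- L %/% pool
    }
  }
  layers[[length(layers) + 1]] <- list(type = "flatten")
  d <- L * C
  if (spec$dense_width > 0) {
    layers[[length(layers) + 1]] <- list(
      type = "dense", W = matrix(stats::rnorm(d * spec$dense_width, 0,
                                              sqrt(2 / d)),
                                 d, spec$dense_width),
      b = numeric(spec$dense_width), dropout = spec$dropout)
    d <- spec$dense_width
  }
  layers[[length(layers) + 1]] <- list(
    type = "output", W = matrix(stats::rnorm(d, 0, sqrt(1 / d)), d, 1),
    b = 0)
  list(layers = layers, p = p, skipped_blocks = skipped)
}

cnn_layer_params <- function(l) {
  if (is.null(l$W)) 0 else length(l$W) + length(l$b)
}

im2col <- function(A, k) {
  d <- dim(A); n <- d[1]; L <- d[2]; C <- d[3]
  L_out <- L - k + 1L
  out <- matrix(0, n * L_out, k * C)
  for (c in seq_len(C)) {
    for (j in seq_len(k)) {
      out[, (c - 1L) * k + j] <- A[, j:(j + L_out - 1L), c]
    }
  }
  out
}

col2im <- function(dXcol, dimA, k) {
  n <- dimA[1]; L <- dimA[2]; C <- dimA[3]
  L_out <- L - k + 1L
  dA <- array(0, dimA)
  for (c in seq_len(C)) {
    for (j in seq_len(k)) {
      dA[, j:(j + L_out - 1L), c] <- dA[, j:(j + L_out - 1L), c] +
        matrix(dXcol[, (c - 1L) * k + j], n, L_out)
    }
  }
  dA
}

# Forward pass. `training` toggles dropout; caches are kept for backprop.
cnn_forward <- function(net, X, training = FALSE) {
  n <- nrow(X)
  A <- array(X, dim = c(n, ncol(X), 1L))
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    if (l$type == "conv") {
      Xcol <- im2col(A, l$kernel)
      Z <- sweep(Xcol %*% l$W, 2, l$b, "+")
      mask <- Z > 0
      Z[!mask] <- 0
      L_out <- dim(A)[2] - l$kernel + 1L
      caches[[i]] <- list(Xcol = Xcol, mask = mask, dimA = dim(A))
      A <- array(Z, dim = c(n, L_out, l$filters))
    } else if (l$type == "pool") {
      w <- l$width
      L_p <- dim(A)[2] %/% w
      idx1 <- seq(1, by = w, length.out = L_p)
      best <- A[, idx1, , drop = FALSE]
      arg <- array(1L, dim(best))
      if (w > 1) for (o in 2:w) {
        cand <- A[, idx1 + (o - 1L), , drop = FALSE]
        upd <- cand > best
        best[upd] <- cand[upd]
        arg[upd] <- o
      }
      caches[[i]] <- list(arg = arg, dimA = dim(A))
      A <- best
    } else if (l$type == "flatten") {
      caches[[i]] <- list(dimA = dim(A))
      A <- matrix(A, n)
    } else if (l$type == "dense") {
      Z <- sweep(A %*% l$W, 2, l$b, "+")
      mask <- Z > 0
      Z[!mask] <- 0
      drop_mask <- NULL
      if (training && l$dropout > 0) {
        drop_mask <- matrix(stats::rbinom(length(Z), 1, 1 - l$dropout),
                            nrow(Z)) / (1 - l$dropout)
        Z <- Z * drop_mask
      }
      caches[[i]] <- list(X = A, mask = mask, drop_mask = drop_mask)
      A <- Z
    } else if (l$type == "output") {
      caches[[i]] <- list(X = A)
      A <- A %*% l$W + l$b
    }
  }
  list(yhat = A, caches = caches)
}

# Backward pass: returns per-layer gradients (same shapes as W/b).
cnn_backward <- function(net, fw, dY) {
  grads <- vector("list", length(net$layers))
  dA <- dY
  for (i in rev(seq_along(net$layers))) {
    l <- net$layers[[i]]
    cc <- fw$caches[[i]]
    if (l$type == "output") {
      grads[[i]] <- list(W = crossprod(cc$X, dA), b = sum(dA))
      dA <- dA %*% t(l$W)
    } else if (l$type == "dense") {
      if (!is.null(cc$drop_mask)) dA <- dA * cc$drop_mask
      dA[!cc$mask] <- 0
      grads[[i]] <- list(W = crossprod(cc$X, dA), b = colSums(dA))
      dA <- dA %*% t(l$W)
    } else if (l$type == "flatten") {
      dA <- array(dA, dim = cc$dimA)
    } else if (l$type == "pool") {
      w <- l$width
      dimA <- cc$dimA
      L_p <- dimA[2] %/% w
      idx1 <- seq(1, by = w, length.out = L_p)
      dIn <- array(0, dimA)
      for (o in seq_len(w)) {
        sel <- cc$arg == o
        slice <- array(0, dim(cc$arg))
        slice[sel] <- dA[sel]
        dIn[, idx1 + (o - 1L), ] <-
          dIn[, idx1 + (o - 1L), , drop = FALSE] + slice
      }
      dA <- dIn
    } else if (l$type == "conv") {
      dZ <- matrix(dA, ncol = l$filters)
      dZ[!cc$mask] <- 0
      grads[[i]] <- list(W = crossprod(cc$Xcol, dZ), b = colSums(dZ))
      dA <- col2im(dZ %*% t(l$W), cc$dimA, l$kernel)
    }
  }
  grads
}

cnn_loss_grad <- function(net, X, y, l2) {
  fw <- cnn_forward(net, X, training = TRUE)
  res <- as.vector(fw$yhat) - y
  n <- length(y)
  dY <- matrix(2 * res / n, ncol = 1)
  grads <- cnn_backward(net, fw, dY)
  loss <- mean(res^2)
  for (i in seq_along(net$layers)) {
    W <- net$layers[[i]]$W
    if (!is.null(W)) {
      loss <- loss + l2 * sum(W^2)
      grads[[i]]$W <- grads[[i]]$W + 2 * l2 * W
    }
  }
  list(loss = loss, grads = grads)
}

cnn_eval_loss <- function(net, X, y) {
  fw <- cnn_forward(net, X, training = FALSE)
  mean((as.vector(fw$yhat) - y)^2)
}

#' Fit the 1-D convolutional regression network
#'
#' Trains the [cnn_spec()] architecture on standardized features and a
#' standardized response with Adam, mini-batches, step-decay learning rate,
#' L2 regularization, dropout, and early stopping (best-weights restore) on a
#' held-out validation fraction of the calibration rows. Fully seeded:
#' identical inputs and seed give identical fits.
#'
#' @param X Predictor matrix or [spectra_tbl()].
#' @param y Numeric response (tannin %).
#' @param spec A [cnn_spec()].
#' @param seed Seed overriding `spec$seed`.
#' @return A `tannin_model` of family `"cnn"` with the trained network,
#'   `history` (per-epoch train/validation loss), `stopped_epoch` and
#'   `best_val_loss`.
#' @export
fit_cnn <- function(X, y, spec = cnn_spec(), seed = NULL) {
  if (inherits(X, "spectra_tbl")) X <- spectra_matrix(X)
  X <- as.matrix(X)
  seed <- seed %||% spec$seed
  n <- nrow(X)
  assert_that_(n >= 5, "too few rows to train the network.")
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[scale < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, center, "-"), 2, scale, "/")
  y_center <- mean(y)
  y_scale <- stats::sd(y)
  if (!is.finite(y_scale) || y_scale < 1e-12) y_scale <- 1
  ys <- (y - y_center) / y_scale

  out <- with_seed_(seed %||% 0L, {
    net <- cnn_build(spec, ncol(X))
    n_val <- max(1L, round(spec$validation_fraction * n))
    perm <- sample.int(n)
    val_idx <- perm[seq_len(n_val)]
    tr_idx <- perm[-seq_len(n_val)]
    Xtr <- Xs[tr_idx, , drop = FALSE]; ytr <- ys[tr_idx]
    Xval <- Xs[val_idx, , drop = FALSE]; yval <- ys[val_idx]

    # Adam state
    mstate <- lapply(net$layers, function(l) {
      if (is.null(l$W)) NULL else list(mW = l$W * 0, vW = l$W * 0,
                                       mb = l$b * 0, vb = l$b * 0)
    })
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t_step <- 0L
    history <- matrix(NA_real_, spec$max_epochs, 2,
                      dimnames = list(NULL, c("train_loss", "val_loss")))
    best_val <- Inf; best_epoch <- 0L; best_layers <- net$layers
    n_tr <- length(tr_idx)
    for (epoch in seq_len(spec$max_epochs)) {
      lr <- spec$learning_rate *
        spec$lr_drop_factor^floor((epoch - 1) / spec$lr_drop_period)
      ord <- sample.int(n_tr)
      ep_loss <- 0; n_batches <- 0L
      for (start in seq(1, n_tr, by = spec$batch_size)) {
        rows <- ord[start:min(start + spec$batch_size - 1, n_tr)]
        lg <- cnn_loss_grad(net, Xtr[rows, , drop = FALSE], ytr[rows], spec$l2)
        if (!is.finite(lg$loss)) {
          abort(sprintf("non-finite training loss at epoch %d; try a smaller learning rate.",
                        epoch))
        }
        ep_loss <- ep_loss + lg$loss; n_batches <- n_batches + 1L
        t_step <- t_step + 1L
        for (i in seq_along(net$layers)) {
          if (is.null(net$layers[[i]]$W)) next
          st <- mstate[[i]]; g <- lg$grads[[i]]
          st$mW <- beta1 * st$mW + (1 - beta1) * g$W
          st$vW <- beta2 * st$vW + (1 - beta2) * g$W^2
          st$mb <- beta1 * st$mb + (1 - beta1) * g$b
          st$vb <- beta2 * st$vb + (1 - beta2) * g$b^2
          mW_hat <- st$mW / (1 - beta1^t_step)
          vW_hat <- st$vW / (1 - beta2^t_step)
          mb_hat <- st$mb / (1 - beta1^t_step)
          vb_hat <- st$vb / (1 - beta2^t_step)
          net$layers[[i]]$W <- net$layers[[i]]$W - lr * mW_hat / (sqrt(vW_hat) + eps)
          net$layers[[i]]$b <- net$layers[[i]]$b - lr * mb_hat / (sqrt(vb_hat) + eps)
          mstate[[i]] <- st
        }
      }
      val_loss <- cnn_eval_loss(net, Xval, yval)
      history[epoch, ] <- c(ep_loss / n_batches, val_loss)
      if (val_loss < best_val - spec$min_delta) {
        best_val <- val_loss; best_epoch <- epoch; best_layers <- net$layers
      }
      if (epoch - best_epoch >= spec$patience) break
    }
    net$layers <- best_layers
    list(net = net,
         history = tibble::as_tibble(history[seq_len(epoch), , drop = FALSE]) |>
           dplyr::mutate(epoch = dplyr::row_number(), .before = 1),
         stopped_epoch = epoch, best_epoch = best_epoch, best_val = best_val)
  })

  new_tannin_model("cnn",
                   net = out$net, spec = spec, history = out$history,
                   stopped_epoch = out$stopped_epoch,
                   best_epoch = out$best_epoch, best_val_loss = out$best_val,
                   center = center, scale = scale,
                   y_center = y_center, y_scale = y_scale,
                   feature_width = ncol(X))
}
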