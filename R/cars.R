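#' CARS configuration
#'
#' Tuning knobs of competitive adaptive reweighted sampling: `n_mc_runs`
#' Monte-Carlo iterations per execution (the study uses 100), a row-subsample
#' ratio per iteration, the cross-validation folds used for RMSECV screening,
#' a cap on PLS components, and an outer stability loop of
#' `stability_repeats` independent executions whose minimum-RMSECV subsets
#' are aggregated by selection frequency.
#'
#' @param n_mc_runs Monte-Carlo iterations N per execution (>= 2, default 100).
#' @param row_sample_ratio Fraction of calibration rows drawn per iteration
#'   (default 0.8).
#' @param cv_folds Folds for RMSECV screening (default 5).
#' @param max_pls_components Cap on PLS latent variables (default 10).
#' @param stability_repeats Outer executions E (default 10).
#' @param frequency_threshold Bands selected in at least this fraction of
#'   executions enter the result (default 0.5).
#' @param seed Integer seed.
#' @return A `cars_config` list.
#' @export
cars_config <- function(n_mc_runs = 100, row_sample_ratio = 0.8, cv_folds = 5,
                        max_pls_components = 10, stability_repeats = 10,
                        frequency_threshold = 0.5, seed = NULL) {
  assert_that_(is_count(n_mc_runs) && n_mc_runs >= 2, "`n_mc_runs` must be >= 2.")
  assert_that_(row_sample_ratio > 0 && row_sample_ratio < 1,
               "`row_sample_ratio` must be in (0, 1).")
  assert_that_(is_count(stability_repeats) && stability_repeats >= 1,
               "`stability_repeats` must be >= 1.")
  assert_that_(frequency_threshold >= 0 && frequency_threshold <= 1,
               "`frequency_threshold` must be in [0, 1].")
  structure(list(n_mc_runs = n_mc_runs, row_sample_ratio = row_sample_ratio,
                 cv_folds = cv_folds, max_pls_components = max_pls_components,
                 stability_repeats = stability_repeats,
                 frequency_threshold = frequency_threshold, seed = seed),
            class = "cars_config")
}

#' Exponential decreasing function of CARS
#'
#' The forced-retention schedule: at Monte-Carlo iteration `i` of `N`, the
#' fraction of the `p` variables kept is `r_i = a * exp(-k * i)` with
#' `a = (p/2)^(1/(N-1))` and `k = log(p/2)/(N-1)`, so that `r_1 = 1` (all
#' variables retainable) and `r_N = 2/p` (two variables survive the schedule).
#'
#' @param i Iteration index, `1 <= i <= N`.
#' @param N Total Monte-Carlo iterations (>= 2).
#' @param p Number of variables (>= 2).
#' @return The retention ratio `r_i`.
#' @examples
#' edf_ratio(1, 100, 646)   # 1
#' edf_ratio(100, 100, 646) # 2/646
#' @export
edf_ratio <- function(i, N, p) {
  assert_that_(is_count(N) && N >= 2, "`N` must be a count >= 2.")
  assert_that_(is_count(p) && p >= 2, "`p` must be a count >= 2.")
  assert_that_(all(i >= 1 & i <= N), "`i` must lie in [1, N].")
  a <- (p / 2)^(1 / (N - 1))
  k <- log(p / 2) / (N - 1)
  a * exp(-k * i)
}

#' One CARS execution
#'
#' Runs `n_mc_runs` Monte-Carlo iterations. Each iteration draws a row
#' subsample, fits PLS on the currently retained variables, converts the
#' absolute regression coefficients to weights `w_j = |b_j| / sum|b_j|`,
#' enforces the EDF retention count by keeping the top-weight variables, then
#' applies adaptive reweighted sampling (a weighted draw with replacement,
#' deduplicated) among the survivors; the retained set is screened by its
#' pooled RMSECV on the full calibration data. The PLS component count is
#' chosen once per execution by inner cross-validation on the full variable
#' set (capped at `max_pls_components`).
#'
#' @param X Calibration predictor matrix or [spectra_tbl()].
#' @param y Calibration response.
#' @param config A [cars_config()].
#' @param seed Seed overriding `config$seed`.
#' @return A `cars_trace`: per-iteration retained index sets, retained counts,
#'   RMSECV values, coefficient vectors, `best_run`, and a `truncated` flag
#'   (set when the retained set collapsed below 2 variables).
#' @export
cars_run <- function(X, y, config = cars_config(), seed = NULL) {
  if (inherits(X, "spectra_tbl")) X <- spectra_matrix(X)
  X <- as.matrix(X)
  p <- ncol(X); n <- nrow(X)
  assert_that_(p >= 2, "CARS needs at least 2 variables.")
  seed <- seed %||% config$seed
  N <- config$n_mc_runs
  with_seed_(seed %||% 0L, {
    folds <- stratified_kfold(y, k = config$cv_folds,
                              seed = derive_seed(seed %||% 0L, "cars_folds"))
    path0 <- rmsecv_path(X, y, folds, config$max_pls_components)
    ncomp <- which.min(path0)
    retained <- seq_len(p)
    subsets <- vector("list", N)
    rmse_cv <- rep(NA_real_, N)
    n_retained <- rep(NA_integer_, N)
    coefs <- vector("list", N)
    truncated <- FALSE
    n_sub <- max(2L, round(config$row_sample_ratio * n))
    for (i in seq_len(N)) {
      n_keep <- min(length(retained), max(2L, round(edf_ratio(i, N, p) * p)))
      rows <- sample.int(n, n_sub)
      kfit <- min(ncomp, length(retained), n_sub - 1L)
      fit <- simpls_fit(X[rows, retained, drop = FALSE], y[rows], kfit)
      b <- abs(as.vector(fit$coefficients[, fit$ncomp]))
      if (sum(b) <= 0) b <- rep(1, length(b))
      w <- b / sum(b)
      # forced retention: keep the top-weight variables up to the EDF count
      keep_ord <- order(w, decreasing = TRUE)[seq_len(n_keep)]
      survivors <- retained[keep_ord]
      w_surv <- w[keep_ord]
      # adaptive reweighted sampling among the survivors
      draw <- sample(survivors, size = n_keep, replace = TRUE,
                     prob = w_surv / sum(w_surv))
      retained_new <- sort(unique(draw))
      if (length(retained_new) < 2) {
        truncated <- TRUE
        break
      }
      retained <- retained_new
      cv_path <- rmsecv_path(X[, retained, drop = FALSE], y, folds,
                             config$max_pls_components)
      subsets[[i]] <- retained
      rmse_cv[i] <- min(cv_path)
      n_retained[i] <- length(retained)
      cf <- numeric(p)
      cf[retained] <- simpls_fit(X[, retained, drop = FALSE], y,
                                 which.min(cv_path))$coefficients[, which.min(cv_path)]
      coefs[[i]] <- cf
    }
    done <- which(!is.na(rmse_cv))
    assert_that_(length(done) >= 1, "CARS collapsed before any iteration completed.")
    # tie-break: minimum RMSECV, then smaller subset, then earlier iteration
    best <- done[order(rmse_cv[done], n_retained[done], done)][1]
    structure(list(subsets = subsets[done], rmsecv = rmse_cv[done],
                   n_retained = n_retained[done],
                   coefficients = coefs[done], iteration = done,
                   best_run = match(best, done), ncomp = ncomp,
                   truncated = truncated, n_variables = p, seed = seed),
              class = "cars_trace")
  })
}

#' @export
print.cars_trace <- function(x, ...) {
  cat(sprintf("<cars_trace: %d iterations over %d variables; best run %d (%d vars, RMSECV %.4f)%s>\n",
              length(x$rmsecv), x$n_variables, x$best_run,
              x$n_retained[x$best_run], x$rmsecv[x$best_run],
              if (x$truncated) "; truncated" else ""))
  invisible(x)
}

#' Stability-selected CARS wavelengths
#'
#' Runs `stability_repeats` independent [cars_run()] executions; each
#' contributes its minimum-RMSECV subset, and bands selected in at least
#' `frequency_threshold` of the executions form the result. If no band
#' clears the threshold the single best execution's subset is used (the
#' `fallback` flag records this).
#'
#' @inheritParams cars_run
#' @param wavelengths Optional wavelength vector (taken from `X` when it is a
#'   [spectra_tbl()]).
#' @return A `cars_result`: `selected` (sorted band indices), `frequency`
#'   (per-band selection frequency over executions), `traces`, `wavelengths`,
#'   `fallback`, `config`.
#' @examples
#' \donttest{
#' ss <- generate_sample_set(generator_params(n_samples = 60, seed = 1))
#' res <- select_features(ss$vnir, ss$reference$tannin,
#'                        cars_config(n_mc_runs = 20, stability_repeats = 2, seed = 1))
#' }
#' @export
select_features <- function(X, y, config = cars_config(), seed = NULL,
                            wavelengths = NULL) {
  if (inherits(X, "spectra_tbl")) {
    wavelengths <- wavelengths %||% spectra_wavelengths(X)
    X <- spectra_matrix(X)
  }
  X <- as.matrix(X)
  seed <- seed %||% config$seed
  E <- config$stability_repeats
  traces <- purrr::map(seq_len(E), function(e) {
    cars_run(X, y, config, seed = derive_seed(seed %||% 0L, "cars_exec", e))
  })
  hits <- integer(ncol(X))
  for (tr in traces) {
    hits[tr$subsets[[tr$best_run]]] <- hits[tr$subsets[[tr$best_run]]] + 1L
  }
  freq <- hits / E
  selected <- which(freq >= config$frequency_threshold & freq > 0)
  if (config$frequency_threshold == 0) selected <- which(freq > 0)
  fallback <- FALSE
  if (length(selected) == 0) {
    fallback <- TRUE
    best_exec <- order(vapply(traces, function(tr) tr$rmsecv[tr$best_run], numeric(1)),
                       vapply(traces, function(tr) tr$n_retained[tr$best_run], numeric(1)))[1]
    selected <- sort(traces[[best_exec]]$subsets[[traces[[best_exec]]$best_run]])
  }
  structure(list(selected = sort(selected), frequency = freq, traces = traces,
                 wavelengths = wavelengths, fallback = fallback,
                 config = config, n_variables = ncol(X)),
            class = "cars_result")
}

#' @export
print.cars_result <- function(x, ...) {
  cat(sprintf("<cars_result: %d of %d bands selected (threshold %.2f over %d executions)%s>\n",
              length(x$selected), x$n_variables, x$config$frequency_threshold,
              x$config$stability_repeats,
              if (x$fallback) "; frequency fallback used" else ""))
  invisible(x)
}

#' @rdname tidy.tannin_model
#' @export
tidy.cars_result <- function(x, ...) {
  tibble::tibble(
    band = seq_len(x$n_variables),
    wavelength = if (is.null(x$wavelengths)) NA_real_ else x$wavelengths,
    frequency = x$frequency,
    selected = seq_len(x$n_variables) %in% x$selected)
}

#' @rdname tidy.tannin_model
#' @export
tidy.cars_trace <- function(x, ...) {
  tibble::tibble(iteration = x$iteration, n_retained = x$n_retained,
                 rmsecv = x$rmsecv,
                 best = seq_along(x$iteration) == x$best_run)
}

#' Restrict a spectra table to CARS-selected bands
#'
#' @param x A [spectra_tbl()].
#' @param result A [select_features()] result (or integer band indices).
#' @return A `spectra_tbl` over the selected bands; the original band indices
#'   are kept in the `selected_index` attribute.
#' @export
apply_selection <- function(x, result) {
  idx <- if (inherits(result, "cars_result")) result$selected else sort(unique(result))
  g <- spectra_grid(x)
  assert_that_(length(idx) >= 1 && all(idx >= 1 & idx <= g$n_bands),
               "selection indices out of range.")
  out <- spectra_tbl(spectra_matrix(x)[, idx, drop = FALSE],
                     sensor_grid(g$sensor_id, g$wavelengths[idx]),
                     sample_ids = x$sample_id)
  attr(out, "selected_index") <- idx
  out
}
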