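#' Hold-out calibration/prediction split
#'
#' Seeded uniform random partition of `n` samples into a calibration set
#' (`round(fraction * n)` samples, used for all fitting and tuning) and a
#' disjoint prediction set evaluated exactly once.
#'
#' @param n Number of samples (>= 2).
#' @param fraction Calibration fraction in (0, 1); the study design is 75/25.
#' @param seed Integer seed.
#' @return A `split_index`: list with integer vectors `calibration` and
#'   `prediction`, plus `fraction` and `seed`.
#' @examples
#' s <- holdout_split(240, seed = 1)
#' lengths(s[c("calibration", "prediction")]) # 180, 60
#' @export
holdout_split <- function(n, fraction = 0.75, seed = NULL) {
  assert_that_(is_count(n) && n >= 2, "`n` must be a count >= 2.")
  assert_that_(fraction > 0 && fraction < 1, "`fraction` must be in (0, 1).")
  n_cal <- round(fraction * n)
  assert_that_(n_cal >= 1 && n_cal <= n - 1,
               "split leaves an empty calibration or prediction set.")
  cal <- with_seed_(seed, sort(sample.int(n, n_cal)))
  structure(list(calibration = cal,
                 prediction = setdiff(seq_len(n), cal),
                 fraction = fraction, seed = seed),
            class = "split_index")
}

#' @export
print.split_index <- function(x, ...) {
  cat(sprintf("<split_index: %d calibration / %d prediction (fraction %.2f)>\n",
              length(x$calibration), length(x$prediction), x$fraction))
  invisible(x)
}

#' Stratified k-fold cross-validation for a continuous target
#'
#' Stratifies on the target's rank: samples are ordered by `y` (ties shuffled
#' under the seed), cut into consecutive rank chunks of size `k`, and each
#' chunk deals exactly one sample to every fold in a seeded random order. Every
#' fold therefore spans the whole target range, folds are disjoint and
#' exhaustive, and fold sizes differ by at most one. Quantile bin edges
#' (`n_bins` strata) are recorded for audit/reporting.
#'
#' @param y Numeric target vector (length >= k).
#' @param k Number of folds (default 5).
#' @param n_bins Number of quantile strata recorded as `bin_edges` (default 5).
#' @param seed Integer seed.
#' @return A `cv_folds`: list with `folds` (list of k integer vectors),
#'   `bin_edges`, `k` and `seed`.
#' @examples
#' f <- stratified_kfold(runif(100), k = 5, seed = 2)
#' lengths(f$folds)
#' @export
stratified_kfold <- function(y, k = 5, n_bins = 5, seed = NULL) {
  n <- length(y)
  assert_that_(is_count(k) && k >= 2, "`k` must be a count >= 2.")
  assert_that_(n >= k, "`k` exceeds the number of samples.")
  probs <- seq(0, 1, length.out = n_bins + 1)
  edges <- unique(stats::quantile(y, probs, names = FALSE, type = 7))
  assignment <- integer(n)
  with_seed_(seed, {
    ord <- order(y, stats::runif(n))  # rank order, ties broken at random
    for (start in seq(1, n, by = k)) {
      chunk <- ord[start:min(start + k - 1, n)]
      assignment[chunk] <- sample.int(k)[seq_along(chunk)]
    }
  })
  structure(list(folds = lapply(seq_len(k), function(f) which(assignment == f)),
                 bin_edges = edges, k = k, seed = seed),
            class = "cv_folds")
}

#' @export
print.cv_folds <- function(x, ...) {
  cat(sprintf("<cv_folds: %d folds of sizes %s>\n", x$k,
              paste(lengths(x$folds), collapse = "/")))
  invisible(x)
}

#' Kennard-Stone hold-out split
#'
#' Distance-based alternative to [holdout_split()], provided as an extension:
#' the calibration set is grown by the classic maximin rule (start from the
#' two most distant samples in predictor space, then repeatedly add the sample
#' farthest from the current calibration set). Deterministic given `X`; the
#' default pipeline uses the seeded random split.
#'
#' @param X Predictor matrix or [spectra_tbl()] used for distances.
#' @param fraction Calibration fraction in (0, 1).
#' @return A `split_index` (with `method = "kennard_stone"`).
#' @export
kennard_stone_split <- function(X, fraction = 0.75) {
  if (inherits(X, "spectra_tbl")) X <- spectra_matrix(X)
  X <- as.matrix(X)
  n <- nrow(X)
  assert_that_(n >= 2, "need at least 2 samples.")
  assert_that_(fraction > 0 && fraction < 1, "`fraction` must be in (0, 1).")
  n_cal <- round(fraction * n)
  assert_that_(n_cal >= 2 && n_cal <= n - 1,
               "split leaves an empty or degenerate partition.")
  d <- as.matrix(stats::dist(X))
  first <- which(d == max(d), arr.ind = TRUE)[1, ]
  sel <- as.integer(first)
  min_d <- pmin(d[, sel[1]], d[, sel[2]])
  while (length(sel) < n_cal) {
    min_d[sel] <- -Inf
    nxt <- which.max(min_d)
    sel <- c(sel, nxt)
    min_d <- pmin(min_d, d[, nxt])
  }
  sel <- sort(sel)
  structure(list(calibration = sel, prediction = setdiff(seq_len(n), sel),
                 fraction = fraction, seed = NULL, method = "kennard_stone"),
            class = "split_index")
}

#' Export a split or fold assignment as a tibble
#'
#' @param x A [holdout_split()] or [stratified_kfold()] result.
#' @return Tibble with `index` and `set`/`fold` columns, suitable for CSV
#'   audit export.
#' @export
split_assignment <- function(x) {
  if (inherits(x, "split_index")) {
    tibble::tibble(index = c(x$calibration, x$prediction),
                   set = rep(c("calibration", "prediction"),
                             c(length(x$calibration), length(x$prediction)))) |>
      dplyr::arrange(.data$index)
  } else if (inherits(x, "cv_folds")) {
    purrr::map_dfr(seq_along(x$folds), function(f) {
      tibble::tibble(index = x$folds[[f]], fold = f)
    }) |>
      dplyr::arrange(.data$index)
  } else {
    abort("`x` must be a split_index or cv_folds.")
  }
}
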