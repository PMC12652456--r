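#' Calibration diagnostics
#'
#' The standard chemometric evaluation statistics, computed from a reference
#' vector and a prediction vector on the same set of samples:
#' \describe{
#'   \item{`r_squared()`}{`1 - sum((yhat - y)^2) / sum((y - mean(y))^2)`.}
#'   \item{`rmse()`}{`sqrt(mean((yhat - y)^2))`.}
#'   \item{`rpd_from_r2()`}{residual predictive deviation `1 / sqrt(1 - R2)`
#'     (so `RPD * sqrt(1 - R2) = 1` identically).}
#'   \item{`bias_and_sep()`}{mean residual (predicted minus reference; negative
#'     bias means underestimation) and the standard error of prediction, the
#'     SD of bias-corrected residuals with `n - 1` in the denominator.}
#' }
#'
#' @param reference Numeric reference values (tannin %).
#' @param predicted Numeric predictions, same length.
#' @return A single number (`r_squared`, `rmse`, `rpd_from_r2`) or a named
#'   list with `bias` and `sep`.
#' @examples
#' r_squared(c(1, 2, 3), c(1, 2, 4)) # 0.5
#' rpd_from_r2(0.80)                 # 2.236
#' @export
r_squared <- function(reference, predicted) {
  check_pair(reference, predicted)
  ss_tot <- sum((reference - mean(reference))^2)
  assert_that_(ss_tot > 0, "reference values have zero variance; R2 undefined.")
  1 - sum((predicted - reference)^2) / ss_tot
}

check_pair <- function(reference, predicted) {
  assert_that_(length(reference) == length(predicted),
               "`reference` and `predicted` lengths differ.")
  assert_that_(length(reference) >= 1 && all(is.finite(reference)) &&
                 all(is.finite(predicted)),
               "inputs must be finite and non-empty.")
}

#' @rdname r_squared
#' @export
rmse <- function(reference, predicted) {
  check_pair(reference, predicted)
  sqrt(mean((predicted - reference)^2))
}

#' @rdname r_squared
#' @param r2 Coefficient of determination, `r2 < 1`.
#' @export
rpd_from_r2 <- function(r2) {
  assert_that_(all(is.finite(r2)) && all(r2 < 1),
               "RPD is unbounded for R2 >= 1.")
  1 / sqrt(1 - r2)
}

#' @rdname r_squared
#' @export
bias_and_sep <- function(reference, predicted) {
  check_pair(reference, predicted)
  n <- length(reference)
  assert_that_(n >= 2, "bias/SEP need at least 2 samples.")
  res <- predicted - reference
  bias <- mean(res)
  list(bias = bias, sep = sqrt(sum((res - bias)^2) / (n - 1)))
}

#' Confidence intervals around predictions
#'
#' Two t-based 95 % intervals derived from the SEP: a mean-level interval
#' `mean(predicted) +/- t * SEP / sqrt(n)` for the average prediction, and a
#' single-prediction interval `mean(predicted) +/- t * SEP` for one new
#' prediction, with `t = t(0.975, n - 1)`. Both are reported because the two
#' interval kinds are easily conflated.
#'
#' @inheritParams r_squared
#' @param level Confidence level (default 0.95).
#' @return Tibble with one row per interval kind (`mean_level`,
#'   `single_prediction`) and columns `lower`, `upper`, `half_width`.
#' @export
confidence_intervals <- function(reference, predicted, level = 0.95) {
  check_pair(reference, predicted)
  n <- length(reference)
  assert_that_(n >= 3, "confidence intervals need at least 3 samples.")
  bs <- bias_and_sep(reference, predicted)
  tq <- stats::qt(1 - (1 - level) / 2, df = n - 1)
  centre <- mean(predicted)
  hw <- c(tq * bs$sep / sqrt(n), tq * bs$sep)
  tibble::tibble(
    interval = c("mean_level", "single_prediction"),
    centre = centre,
    half_width = hw,
    lower = centre - hw,
    upper = centre + hw)
}

#' Qualitative interpretation of R2 and RPD
#'
#' The conventional reading of the diagnostics: R2 below 0.6 is poor, 0.6 to
#' 0.8 good, above 0.8 excellent; RPD below 1.5 insufficient, 1.5 to 2.0
#' adequate for quantitative screening, above 2.0 outstanding. Band
#' boundaries use a closed-left convention (0.8 falls in the upper band,
#' 1.5 in the middle band).
#'
#' @param r2,rpd Numeric values.
#' @return Named character vector with `r2_label` and `rpd_label`.
#' @examples
#' interpret_performance(0.83, 2.42)
#' @export
interpret_performance <- function(r2, rpd) {
  r2_label <- ifelse(r2 < 0.6, "poor", ifelse(r2 < 0.8, "good", "excellent"))
  rpd_label <- ifelse(rpd < 1.5, "insufficient",
                      ifelse(rpd < 2.0, "adequate", "outstanding"))
  c(r2_label = unname(r2_label), rpd_label = unname(rpd_label))
}

#' One-row metrics report for a prediction set
#'
#' Data-frame-first wrapper assembling all diagnostics for one partition:
#' R2, RMSE, RPD, bias, SEP, both 95 % intervals and the qualitative labels.
#'
#' @param data Data frame holding the columns named by `truth`/`estimate`.
#' @param truth,estimate Column names (tidyselect-style strings) of the
#'   reference and predicted values.
#' @param set Partition label (`"calibration"`, `"cv"` or `"prediction"`).
#' @return One-row tibble.
#' @examples
#' d <- data.frame(y = c(1, 2, 3), yhat = c(1.1, 1.9, 3.2))
#' metrics_report(d, "y", "yhat", set = "prediction")
#' @export
metrics_report <- function(data, truth = "tannin", estimate = ".pred",
                           set = "prediction") {
  y <- data[[truth]]; yhat <- data[[estimate]]
  assert_that_(!is.null(y) && !is.null(yhat),
               "`truth`/`estimate` columns not found in `data`.")
  r2 <- r_squared(y, yhat)
  rm <- rmse(y, yhat)
  rpd <- if (r2 < 1) rpd_from_r2(r2) else Inf
  bs <- bias_and_sep(y, yhat)
  ci <- if (length(y) >= 3) confidence_intervals(y, yhat) else NULL
  labels <- interpret_performance(r2, rpd)
  tibble::tibble(
    set = set, n = length(y), r2 = r2, rmse = rm, rpd = rpd,
    bias = bs$bias, sep = bs$sep,
    ci_mean_lower = if (is.null(ci)) NA_real_ else ci$lower[1],
    ci_mean_upper = if (is.null(ci)) NA_real_ else ci$upper[1],
    ci_single_lower = if (is.null(ci)) NA_real_ else ci$lower[2],
    ci_single_upper = if (is.null(ci)) NA_real_ else ci$upper[2],
    r2_label = labels[["r2_label"]], rpd_label = labels[["rpd_label"]])
}

#' One-way ANOVA with Tukey HSD on model errors
#'
#' Compares replicate prediction errors (RMSEP) across model families:
#' classical one-way ANOVA F test followed by Tukey's honestly-significant-
#' difference pairwise comparisons on the group means.
#'
#' @param data Data frame with a grouping column and a value column, or a
#'   named list of numeric replicate vectors.
#' @param group,value Column names when `data` is a data frame.
#' @return A `comparison_report`: list with `anova` (one-row tibble: `f`,
#'   `df1`, `df2`, `p_value`) and `tukey` (pairwise tibble: `comparison`,
#'   `diff`, `lower`, `upper`, `p_adj`).
#' @examples
#' compare_models_anova(list(a = c(1, 2, 3), b = c(4, 5, 6)))
#' @export
compare_models_anova <- function(data, group = "family", value = "rmsep") {
  if (!is.data.frame(data)) {
    assert_that_(is.list(data) && length(data) >= 2,
                 "need at least two groups.")
    data <- purrr::imap_dfr(data, ~ tibble::tibble(family = .y, rmsep = .x))
    group <- "family"; value <- "rmsep"
  }
  g <- factor(data[[group]])
  v <- data[[value]]
  assert_that_(nlevels(g) >= 2, "need at least two groups.")
  assert_that_(all(table(g) >= 2), "every group needs >= 2 replicates.")
  assert_that_(any(tapply(v, g, stats::var) > 0),
               "zero within-group variance in every group; ANOVA undefined.")
  fit <- stats::aov(v ~ g)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$g
  structure(
    list(anova = tibble::tibble(f = an[["F value"]][1],
                                df1 = an[["Df"]][1], df2 = an[["Df"]][2],
                                p_value = an[["Pr(>F)"]][1]),
         tukey = tibble::tibble(comparison = rownames(tk),
                                diff = tk[, "diff"], lower = tk[, "lwr"],
                                upper = tk[, "upr"], p_adj = tk[, "p adj"]),
         groups = levels(g)),
    class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  a <- x$anova
  cat(sprintf("<comparison_report: F(%d, %d) = %.2f, p = %.3g>\n",
              a$df1, a$df2, a$f, a$p_value))
  print(x$tukey)
  invisible(x)
}

#' @rdname tidy.tannin_model
#' @export
tidy.comparison_report <- function(x, ...) x$tukey

#' @rdname tidy.tannin_model
#' @export
glance.comparison_report <- function(x, ...) x$anova

#' Residual summary for a prediction set
#'
#' Residual (predicted minus reference) moments — mean, SD, skewness, excess
#' kurtosis — plus a Shapiro-Wilk normality p-value, and the per-sample
#' residual table for scatter/histogram displays. Degenerate (constant)
#' residuals get skewness/kurtosis 0 with `degenerate = TRUE`.
#'
#' @inheritParams r_squared
#' @return A list with `summary` (one-row tibble) and `residuals` (tibble
#'   with `reference`, `predicted`, `residual`).
#' @export
residual_summary <- function(reference, predicted) {
  check_pair(reference, predicted)
  n <- length(reference)
  assert_that_(n >= 8, "residual summary needs at least 8 samples.")
  res <- predicted - reference
  degenerate <- stats::sd(res) < 1e-12
  skew <- if (degenerate) 0 else e1071::skewness(res, type = 2)
  kurt <- if (degenerate) 0 else e1071::kurtosis(res, type = 2)
  sw <- if (degenerate) NA_real_ else stats::shapiro.test(res)$p.value
  structure(
    list(summary = tibble::tibble(n = n, mean = mean(res), sd = stats::sd(res),
                                  skewness = skew, excess_kurtosis = kurt,
                                  shapiro_p = sw, degenerate = degenerate),
         residuals = tibble::tibble(reference = reference, predicted = predicted,
                                    residual = res)),
    class = "residual_summary")
}
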