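test_that("R2, RMSE and RPD match their definitions", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(r_squared(c(1, 2, 3), rep(2, 3)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_error(r_squared(c(2, 2), c(1, 3)), "zero variance")

  expect_equal(rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse(c(0, 0), c(1, -1)), 1)
  ref <- withr::with_seed(1, runif(10)); est <- withr::with_seed(2, runif(10))
  expect_equal(rmse(ref, est), sqrt(sum((est - ref)^2) / 10), tolerance = 1e-12)

  expect_equal(rpd_from_r2(0), 1)
  expect_error(rpd_from_r2(1), "unbounded")
  # identity RPD^2 * (1 - R2) = 1 and strict monotonicity
  r2s <- seq(-0.5, 0.99, by = 0.01)
  expect_equal(rpd_from_r2(r2s)^2 * (1 - r2s), rep(1, length(r2s)),
               tolerance = 1e-12)
  expect_true(all(diff(rpd_from_r2(r2s)) > 0))
})

test_that("calibration-set R2 is consistent with RMSE and reference variance", {
  ref <- withr::with_seed(3, rnorm(40, 1.2, 0.7))
  est <- withr::with_seed(4, ref + rnorm(40, 0, 0.3))
  r2 <- r_squared(ref, est)
  expect_equal(r2, 1 - rmse(ref, est)^2 * 40 / sum((ref - mean(ref))^2),
               tolerance = 1e-12)
})

test_that("bias and SEP follow the bias-corrected residual definitions", {
  expect_equal(bias_and_sep(c(1, 2), c(1, 2)), list(bias = 0, sep = 0))
  expect_equal(bias_and_sep(c(1, 2, 3), c(1.5, 2.5, 3.5)),
               list(bias = 0.5, sep = 0))
  got <- bias_and_sep(rep(0, 4), c(0.1, -0.1, 0.3, -0.3))
  expect_equal(got$bias, 0)
  expect_equal(got$sep, sqrt(0.2 / 3), tolerance = 1e-12)
})

test_that("confidence intervals behave like t intervals", {
  ref <- c(1, 2, 3); est <- ref
  ci <- confidence_intervals(ref, est)
  expect_equal(ci$lower, ci$upper)  # SEP = 0 collapses both intervals

  res <- withr::with_seed(5, rnorm(60, 0, 0.3))
  ref <- withr::with_seed(6, runif(60, 0.5, 2.5))
  ci60 <- confidence_intervals(ref, ref + res)
  ci30 <- confidence_intervals(ref[1:30], ref[1:30] + res[1:30])
  # mean-level width shrinks roughly as 1/sqrt(n); single-prediction does not
  ratio_mean <- ci30$half_width[1] / ci60$half_width[1]
  ratio_single <- ci30$half_width[2] / ci60$half_width[2]
  expect_gt(ratio_mean, ratio_single)

  # the mean-level half-width matches a residual bootstrap of the bias
  boot <- withr::with_seed(7, replicate(10000, mean(sample(res, replace = TRUE))))
  boot_half <- unname(diff(quantile(boot, c(0.025, 0.975)))) / 2
  expect_lt(abs(ci60$half_width[1] / boot_half - 1), 0.1)
})

test_that("qualitative labels use the closed-left band convention", {
  expect_identical(interpret_performance(0.83, 2.42),
                   c(r2_label = "excellent", rpd_label = "outstanding"))
  expect_identical(interpret_performance(0.59, 1.2),
                   c(r2_label = "poor", rpd_label = "insufficient"))
  expect_identical(interpret_performance(0.6, 1.5),
                   c(r2_label = "good", rpd_label = "adequate"))
  expect_identical(interpret_performance(0.8, 2.0),
                   c(r2_label = "excellent", rpd_label = "outstanding"))
})

test_that("metrics_report assembles all diagnostics in one row", {
  d <- tibble::tibble(tannin = withr::with_seed(8, runif(30, 0.1, 2.5)))
  d$.pred <- d$tannin + withr::with_seed(9, rnorm(30, 0, 0.2))
  rep <- metrics_report(d, set = "prediction")
  expect_equal(rep$n, 30)
  expect_equal(rep$r2, r_squared(d$tannin, d$.pred))
  expect_equal(rep$rpd, rpd_from_r2(rep$r2))
  expect_equal(rep$bias, mean(d$.pred - d$tannin))
  expect_true(rep$ci_single_lower < rep$ci_mean_lower)
})

test_that("one-way ANOVA and Tukey HSD match hand-computed sums of squares", {
  got <- compare_models_anova(list(a = c(2, 4), b = c(6, 8)))
  expect_equal(got$anova$f, 8)
  expect_equal(c(got$anova$df1, got$anova$df2), c(1, 2))

  # strong separation clears a stringent threshold
  sep <- compare_models_anova(list(a = c(1, 2, 3), b = c(11, 12, 13)))
  expect_gt(sep$anova$f, qf(0.999, 1, 4))
  expect_lt(sep$anova$p_value, 0.001)

  # identical replicate sets across groups: F ~ 0, Tukey p ~ 1
  same <- compare_models_anova(list(a = c(1, 2, 3), b = c(1, 2, 3),
                                    c = c(1, 2, 3)))
  expect_lt(same$anova$f, 1e-10)
  expect_true(all(same$tukey$p_adj > 0.999))

  expect_error(compare_models_anova(list(a = c(1, 1), b = c(1, 1))),
               "zero within-group variance")
})

test_that("null ANOVA p-values are uniform", {
  ps <- vapply(1:200, function(s) {
    g <- withr::with_seed(s, list(a = rnorm(10), b = rnorm(10), c = rnorm(10)))
    compare_models_anova(g)$anova$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("residual summaries report moments, normality and degeneracy", {
  res <- withr::with_seed(10, rnorm(1000))
  ref <- withr::with_seed(11, runif(1000, 0, 2.5))
  rs <- residual_summary(ref, ref + res)
  expect_lt(abs(rs$summary$skewness), 0.2)
  expect_lt(abs(rs$summary$excess_kurtosis), 0.5)
  expect_equal(rs$summary$mean, bias_and_sep(ref, ref + res)$bias)

  flat <- residual_summary(ref[1:10], ref[1:10] + 0.2)
  expect_true(flat$summary$degenerate)
  expect_equal(flat$summary$skewness, 0)
})
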