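test_that("standard curves are exact least squares and invert correctly", {
  ident <- fit_standard_curve(data.frame(concentration = c(0, 1),
                                         absorbance = c(0, 1)))
  expect_equal(concentration_from_absorbance(ident, 0.37), 0.37)

  collinear <- fit_standard_curve(data.frame(concentration = 0:2,
                                             absorbance = c(0, 2, 4)))
  expect_equal(collinear$slope, 2)
  expect_equal(collinear$intercept, 0)

  # noisy points against the closed-form normal equations
  pts <- withr::with_seed(8, data.frame(concentration = runif(5, 0, 10),
                                        absorbance = NA))
  pts$absorbance <- 0.3 + 0.12 * pts$concentration +
    withr::with_seed(9, rnorm(5, 0, 0.02))
  fit <- fit_standard_curve(pts)
  x <- pts$concentration; y <- pts$absorbance
  slope_cf <- (sum(x * y) - length(x) * mean(x) * mean(y)) /
    (sum(x^2) - length(x) * mean(x)^2)
  expect_equal(fit$slope, slope_cf, tolerance = 1e-10)
  expect_equal(fit$intercept, mean(y) - slope_cf * mean(x), tolerance = 1e-10)

  expect_error(fit_standard_curve(data.frame(concentration = c(1, 1),
                                             absorbance = c(0, 1))),
               "degenerate")
})

test_that("the assay formula gives dry-matter tannin percent", {
  curve <- fit_standard_curve(data.frame(concentration = 0:1, absorbance = 0:1))
  # c = 5 mg/mL in a 1000 mg sample at zero moisture -> 1.0 %
  expect_equal(tannin_from_assay(curve, 5, mass_mg = 1000, moisture_pct = 0), 1)
  # zero concentration -> zero tannin regardless of mass/moisture
  expect_equal(tannin_from_assay(curve, 0, 500, 12), 0)
  # halving the dry matter doubles the reported content
  expect_equal(tannin_from_assay(curve, 5, 1000, 50),
               2 * tannin_from_assay(curve, 5, 1000, 0))
  # strictly increasing in moisture on [0, 100)
  hs <- c(0, 20, 40, 60, 80, 99)
  ts <- vapply(hs, function(h) tannin_from_assay(curve, 2, 800, h), numeric(1))
  expect_true(all(diff(ts) > 0))
  expect_error(tannin_from_assay(curve, 5, 1000, 100), "\\[0, 100\\)")
  expect_error(tannin_from_assay(curve, 5, 0, 10), "> 0")
})

test_that("replicates average arithmetically before curve inversion", {
  expect_equal(average_replicates(c(1, 1, 1)), 1)
  expect_equal(average_replicates(c(0.9, 1.1)), 1)
  v <- withr::with_seed(3, runif(3))
  expect_equal(average_replicates(v), sum(v) / 3)
  expect_error(average_replicates(numeric(0)), "non-empty")
  curve <- fit_standard_curve(data.frame(concentration = 0:1, absorbance = 0:1))
  expect_equal(tannin_from_assay(curve, c(4, 5, 6), 1000, 0),
               tannin_from_assay(curve, 5, 1000, 0))
})
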