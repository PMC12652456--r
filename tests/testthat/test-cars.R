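test_that("the EDF schedule hits its closed-form endpoints exactly", {
  for (N in c(2, 50, 100)) {
    for (p in c(2, 148, 646)) {
      expect_equal(edf_ratio(1, N, p), 1, tolerance = 1e-12)
      expect_equal(edf_ratio(N, N, p), 2 / p, tolerance = 1e-12)
    }
  }
  # interior value against a direct evaluation of the formula
  N <- 100; p <- 646; i <- 50
  a <- (p / 2)^(1 / (N - 1)); k <- log(p / 2) / (N - 1)
  expect_equal(edf_ratio(i, N, p), a * exp(-k * i), tolerance = 1e-12)
  expect_error(edf_ratio(1, 1, 10), ">= 2")
  expect_error(edf_ratio(0, 10, 10), "in \\[1, N\\]")
})

test_that("retained-variable counts never increase along a run", {
  for (seed in 1:3) {
    d <- planted_data(80, 40, informative = c(3, 17, 31), seed = seed)
    tr <- cars_run(d$X, d$y, cars_config(n_mc_runs = 25, seed = seed))
    expect_false(is.unsorted(rev(tr$n_retained)))
    expect_true(all(tr$rmsecv > 0 & is.finite(tr$rmsecv)))
    expect_equal(tr$rmsecv[tr$best_run], min(tr$rmsecv))
    # every recorded subset is within dimension and duplicates-free
    for (s in tr$subsets) {
      expect_true(all(s >= 1 & s <= 40))
      expect_identical(s, sort(unique(s)))
    }
  }
})

test_that("CARS recovers planted informative bands", {
  d <- planted_data(200, 200, informative = seq(10, 100, by = 10),
                    noise_sd = 0.3, seed = 11)
  tr <- cars_run(d$X, d$y, cars_config(n_mc_runs = 100, seed = 1))
  best <- tr$subsets[[tr$best_run]]
  expect_gte(sum(d$informative %in% best), 8)
})

test_that("pure-noise responses yield no strong selection artifact", {
  ratios <- vapply(1:10, function(s) {
    X <- withr::with_seed(s, matrix(rnorm(200 * 20), 200))
    y <- withr::with_seed(s + 100, rnorm(200))
    tr <- cars_run(X, y, cars_config(n_mc_runs = 30, max_pls_components = 5,
                                     seed = s))
    folds <- stratified_kfold(y, seed = tanninfuse:::derive_seed(s, "cars_folds"))
    full <- min(tanninfuse:::rmsecv_path(X, y, folds, 5))
    min(tr$rmsecv) / full
  }, numeric(1))
  expect_gte(median(ratios), 0.9)
})

test_that("stability selection reduces to and aggregates single runs", {
  d <- planted_data(100, 50, informative = c(5, 25, 45), seed = 21)
  cfg1 <- cars_config(n_mc_runs = 20, stability_repeats = 1, seed = 3)
  res1 <- select_features(d$X, d$y, cfg1)
  tr1 <- cars_run(d$X, d$y, cfg1,
                  seed = tanninfuse:::derive_seed(3, "cars_exec", 1))
  expect_identical(res1$selected, sort(tr1$subsets[[tr1$best_run]]))

  cfg0 <- cars_config(n_mc_runs = 20, stability_repeats = 4,
                      frequency_threshold = 0, seed = 3)
  res0 <- select_features(d$X, d$y, cfg0)
  union_sets <- sort(unique(unlist(lapply(res0$traces, function(tr) {
    tr$subsets[[tr$best_run]]
  }))))
  expect_identical(res0$selected, union_sets)
  expect_true(all(res0$frequency >= 0 & res0$frequency <= 1))
})

test_that("stability selection keeps planted bands with few false positives", {
  d <- planted_data(200, 200, informative = seq(10, 100, by = 10),
                    noise_sd = 0.3, seed = 11)
  res <- select_features(d$X, d$y,
                         cars_config(n_mc_runs = 100, stability_repeats = 10,
                                     frequency_threshold = 0.5, seed = 1))
  expect_true(all(d$informative %in% res$selected))
  expect_lte(sum(!res$selected %in% d$informative), 10)
})

test_that("selected features keep PLS cross-validation competitive", {
  wins <- 0
  for (seed in 1:3) {
    ss <- small_sample_set(n = 100, seed = seed)
    y <- ss$reference$tannin
    res <- select_features(ss$vnir, y,
                           cars_config(n_mc_runs = 30, stability_repeats = 3,
                                       seed = seed))
    folds <- stratified_kfold(y, seed = seed)
    X <- spectra_matrix(ss$vnir)
    full <- min(tanninfuse:::rmsecv_path(X, y, folds, 10))
    sel <- min(tanninfuse:::rmsecv_path(X[, res$selected, drop = FALSE], y,
                                        folds, 10))
    wins <- wins + (sel <= 1.05 * full)
  }
  expect_gte(wins, 2)
})

test_that("selection restricts tables with provenance intact", {
  ss <- small_sample_set(n = 20, seed = 9)
  res <- select_features(ss$swir, ss$reference$tannin, fast_cars(9))
  sub <- apply_selection(ss$swir, res)
  expect_equal(spectra_grid(sub)$n_bands, length(res$selected))
  expect_identical(attr(sub, "selected_index"), res$selected)
  expect_equal(spectra_matrix(sub),
               spectra_matrix(ss$swir)[, res$selected, drop = FALSE])
})
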