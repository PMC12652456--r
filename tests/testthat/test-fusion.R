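test_that("data-layer fusion splices the full grids to 794 columns", {
  ss <- generate_sample_set(generator_params(n_samples = 3, seed = 1))
  fused <- concat_data_layer(ss$vnir, ss$swir)
  expect_equal(spectra_grid(fused)$n_bands, 646 + 148)
  prov <- spectra_provenance(fused)
  expect_equal(sum(prov$sensor == "VNIR"), 646)
  expect_equal(sum(prov$sensor == "SWIR"), 148)
  expect_identical(attr(fused, "layer"), "data")
})

test_that("every fused cell equals its source cell under the provenance map", {
  g1 <- sensor_grid("VNIR", c(500, 600, 700))
  g2 <- sensor_grid("SWIR", c(1000, 1200))
  a <- spectra_tbl(matrix(1:6 / 10, 2), g1, c("x", "y"))
  b <- spectra_tbl(matrix(7:10 / 10, 2), g2, c("x", "y"))
  fused <- concat_data_layer(a, b)
  m <- spectra_matrix(fused)
  prov <- spectra_provenance(fused)
  src <- list(VNIR = spectra_matrix(a), SWIR = spectra_matrix(b))
  for (j in seq_len(nrow(prov))) {
    expect_equal(m[, prov$column[j]],
                 src[[prov$sensor[j]]][, prov$band_index[j]])
  }
})

test_that("feature-layer fusion carries original band indices", {
  ss <- small_sample_set(n = 12, seed = 3)
  vf <- apply_selection(ss$vnir, c(5L, 20L, 60L))
  sf <- apply_selection(ss$swir, c(2L, 30L))
  fused <- concat_feature_layer(vf, sf)
  expect_equal(spectra_grid(fused)$n_bands, 5)
  prov <- spectra_provenance(fused)
  expect_identical(prov$band_index, c(5L, 20L, 60L, 2L, 30L))
  expect_identical(attr(fused, "layer"), "feature")
  # single-band subsets from both sensors: 2 columns, distinct provenance
  tiny <- concat_feature_layer(apply_selection(ss$vnir, 10L),
                               apply_selection(ss$swir, 10L))
  expect_equal(spectra_grid(tiny)$n_bands, 2)
  expect_identical(spectra_provenance(tiny)$sensor, c("VNIR", "SWIR"))
})

test_that("de-fusion inverts fusion losslessly", {
  ss <- small_sample_set(n = 8, seed = 4)
  vf <- apply_selection(ss$vnir, c(3L, 9L))
  sf <- apply_selection(ss$swir, c(1L, 7L, 11L))
  fused <- concat_feature_layer(vf, sf)
  parts <- defuse(fused)
  expect_equal(spectra_matrix(parts$VNIR), spectra_matrix(vf))
  expect_equal(spectra_matrix(parts$SWIR), spectra_matrix(sf))
  expect_equal(spectra_wavelengths(parts$SWIR), spectra_wavelengths(sf))
})

test_that("fusion refuses mismatched samples and commutes with row order", {
  ss <- small_sample_set(n = 6, seed = 5)
  bad <- ss$swir
  bad$sample_id[2] <- "intruder"
  expect_error(concat_data_layer(ss$vnir, bad), "sample ids differ")

  perm <- c(4, 1, 6, 2, 5, 3)
  reorder <- function(tbl) {
    spectra_tbl(spectra_matrix(tbl)[perm, ], spectra_grid(tbl),
                tbl$sample_id[perm])
  }
  f1 <- spectra_matrix(concat_data_layer(ss$vnir, ss$swir))[perm, ]
  f2 <- spectra_matrix(concat_data_layer(reorder(ss$vnir), reorder(ss$swir)))
  expect_equal(unname(f1), unname(f2))
})
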