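#' Fuse two sensors' spectra by concatenation
#'
#' Data-layer fusion splices the full VNIR and SWIR spectra along the
#' wavelength axis into one continuous predictor matrix (646 + 148 = 794
#' columns at the default grids); feature-layer fusion does the same with the
#' CARS-selected band subsets of each sensor. Values are copied unchanged
#' (no per-block rescaling) and every fused column carries provenance:
#' source sensor, original band index, wavelength.
#'
#' @param vnir,swir [spectra_tbl()]s with identical sample ids in identical
#'   order. For `concat_feature_layer()` these are the selected-band tables
#'   from [apply_selection()] (their `selected_index` attribute, when present,
#'   supplies the original pre-selection band indices).
#' @return A `fused_tbl` (a [spectra_tbl()] with `layer` and `provenance`
#'   attributes; bands ordered VNIR then SWIR).
#' @examples
#' ss <- generate_sample_set(generator_params(n_samples = 3, seed = 1))
#' f <- concat_data_layer(ss$vnir, ss$swir)
#' ncol(spectra_matrix(f)) # 794
#' @export
concat_data_layer <- function(vnir, swir) {
  fuse_blocks(vnir, swir, layer = "data")
}

#' @rdname concat_data_layer
#' @export
concat_feature_layer <- function(vnir, swir) {
  assert_that_(spectra_grid(vnir)$n_bands >= 1 && spectra_grid(swir)$n_bands >= 1,
               "feature-layer fusion received an empty subset.")
  fuse_blocks(vnir, swir, layer = "feature")
}

fuse_blocks <- function(a, b, layer) {
  ga <- spectra_grid(a); gb <- spectra_grid(b)
  assert_that_(nrow(a) == nrow(b),
               sprintf("sample counts differ: %d vs %d.", nrow(a), nrow(b)))
  mismatch <- which(a$sample_id != b$sample_id)
  if (length(mismatch) > 0) {
    abort(sprintf("sample ids differ at position(s) %s.",
                  paste(utils::head(mismatch, 5), collapse = ", ")))
  }
  prov <- dplyr::bind_rows(
    tibble::tibble(column = seq_len(ga$n_bands), sensor = ga$sensor_id,
                   band_index = attr(a, "selected_index") %||% seq_len(ga$n_bands),
                   wavelength = ga$wavelengths),
    tibble::tibble(column = ga$n_bands + seq_len(gb$n_bands), sensor = gb$sensor_id,
                   band_index = attr(b, "selected_index") %||% seq_len(gb$n_bands),
                   wavelength = gb$wavelengths)
  )
  values <- cbind(spectra_matrix(a), spectra_matrix(b))
  # fused wavelength axes overlap conceptually but the grids are disjoint
  # (VNIR tops out at 900 nm, SWIR starts at 950 nm), so the fused grid stays
  # strictly increasing at the default configuration; for exotic grids we keep
  # the raw concatenation order and label columns by position
  grid <- if (all(diff(prov$wavelength) > 0)) {
    sensor_grid("FUSED", prov$wavelength)
  } else {
    sensor_grid("FUSED", seq_along(prov$wavelength))
  }
  out <- spectra_tbl(values, grid, sample_ids = a$sample_id)
  attr(out, "provenance") <- prov
  attr(out, "layer") <- layer
  class(out) <- c("fused_tbl", class(out))
  out
}

#' @export
print.fused_tbl <- function(x, ...) {
  prov <- spectra_provenance(x)
  counts <- table(prov$sensor)
  cat(sprintf("# fused_tbl (%s layer): %d samples x %d columns (%s)\n",
              attr(x, "layer") %||% "?", nrow(x), nrow(prov),
              paste(sprintf("%s: %d", names(counts), as.integer(counts)),
                    collapse = ", ")))
  invisible(x)
}

#' Recover per-sensor blocks from a fused matrix
#'
#' Inverts fusion losslessly via the provenance map: every fused column goes
#' back to its source sensor and original band index.
#'
#' @param fused A `fused_tbl` from [concat_data_layer()] or
#'   [concat_feature_layer()].
#' @return Named list of [spectra_tbl()]s, one per source sensor.
#' @export
defuse <- function(fused) {
  prov <- spectra_provenance(fused)
  assert_that_(!is.null(prov), "`fused` carries no provenance; cannot de-fuse.")
  m <- spectra_matrix(fused)
  out <- lapply(split(prov, prov$sensor), function(pr) {
    pr <- pr[order(pr$column), ]
    spectra_tbl(m[, pr$column, drop = FALSE],
                sensor_grid(pr$sensor[1], pr$wavelength),
                sample_ids = fused$sample_id)
  })
  out[unique(prov$sensor)]
}
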