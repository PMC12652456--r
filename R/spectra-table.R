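#' Sensor wavelength grids
#'
#' A sensor grid binds a sensor label to a strictly increasing wavelength
#' vector (nm). The two study sensors are the defaults: a VNIR lens trimmed
#' to 430--900 nm (646 bands) and a SWIR lens trimmed to 950--1650 nm
#' (148 bands).
#'
#' @param sensor_id `"VNIR"` or `"SWIR"` (free labels such as `"FUSED"` are
#'   allowed for derived grids).
#' @param wavelengths Strictly increasing numeric vector of band centres (nm).
#' @return A `sensor_grid` object (list with `sensor_id`, `wavelengths`,
#'   `n_bands`).
#' @examples
#' g <- vnir_grid()
#' g$n_bands # 646
#' @export
sensor_grid <- function(sensor_id, wavelengths) {
  wavelengths <- as.numeric(wavelengths)
  assert_that_(length(wavelengths) >= 1 && all(is.finite(wavelengths)),
               "`wavelengths` must be finite and non-empty.")
  assert_that_(all(diff(wavelengths) > 0),
               "`wavelengths` must be strictly increasing.")
  structure(
    list(sensor_id = as.character(sensor_id),
         wavelengths = wavelengths,
         n_bands = length(wavelengths)),
    class = "sensor_grid"
  )
}

#' @rdname sensor_grid
#' @export
vnir_grid <- function() {
  sensor_grid("VNIR", seq(430, 900, length.out = 646))
}

#' @rdname sensor_grid
#' @export
swir_grid <- function() {
  sensor_grid("SWIR", seq(950, 1650, length.out = 148))
}

#' @export
print.sensor_grid <- function(x, ...) {
  cat(sprintf("<sensor_grid %s: %d bands, %.1f-%.1f nm>\n",
              x$sensor_id, x$n_bands, min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' Spectra tables
#'
#' The unit every pipeline stage consumes: a tibble with a `sample_id`
#' column followed by one numeric reflectance column per band, the column
#' names being wavelengths in nm (3 decimals). The sensor grid travels as
#' attributes so downstream stages never re-guess it.
#'
#' @param values Numeric samples-by-bands matrix of reflectance.
#' @param grid A [sensor_grid()] whose band count matches `ncol(values)`.
#' @param sample_ids Character vector of sample identifiers (default
#'   `S001 ...`).
#' @return A `spectra_tbl` (tibble subclass).
#' @examples
#' m <- matrix(runif(15), nrow = 3)
#' s <- spectra_tbl(m, sensor_grid("VNIR", c(500, 550, 600, 650, 700)))
#' spectra_matrix(s)
#' @export
spectra_tbl <- function(values, grid, sample_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  assert_that_(inherits(grid, "sensor_grid"), "`grid` must be a sensor_grid.")
  assert_that_(ncol(values) == grid$n_bands,
               sprintf("values has %d columns but grid has %d bands.",
                       ncol(values), grid$n_bands))
  assert_that_(all(is.finite(values)), "reflectance values must be finite.")
  if (is.null(sample_ids)) {
    sample_ids <- sprintf("S%03d", seq_len(nrow(values)))
  }
  assert_that_(length(sample_ids) == nrow(values),
               "`sample_ids` length must equal the number of rows.")
  colnames(values) <- format_wl(grid$wavelengths)
  out <- tibble::as_tibble(as.data.frame(values, check.names = FALSE))
  out <- dplyr::bind_cols(tibble::tibble(sample_id = as.character(sample_ids)), out)
  new_spectra_tbl(out, grid)
}

new_spectra_tbl <- function(tbl, grid, provenance = NULL) {
  structure(tbl,
            class = c("spectra_tbl", class(tibble::tibble())),
            grid = grid,
            provenance = provenance)
}

format_wl <- function(wl) sprintf("%.3f", wl)

#' @rdname spectra_tbl
#' @param x A `spectra_tbl`.
#' @export
spectra_matrix <- function(x) {
  stopifnot(inherits(x, "data.frame"))
  m <- as.matrix(x[, setdiff(names(x), "sample_id"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- x$sample_id
  m
}

#' @rdname spectra_tbl
#' @export
spectra_grid <- function(x) {
  g <- attr(x, "grid")
  if (!is.null(g)) return(g)
  # attribute was stripped (e.g. by a dplyr verb): rebuild from column names
  sensor_grid("UNKNOWN", as.numeric(setdiff(names(x), "sample_id")))
}

#' @rdname spectra_tbl
#' @export
spectra_wavelengths <- function(x) spectra_grid(x)$wavelengths

#' @rdname spectra_tbl
#' @export
spectra_provenance <- function(x) attr(x, "provenance")

#' @export
print.spectra_tbl <- function(x, ...) {
  g <- spectra_grid(x)
  cat(sprintf("# spectra_tbl: %d samples x %d bands [%s, %.1f-%.1f nm]\n",
              nrow(x), g$n_bands, g$sensor_id,
              min(g$wavelengths), max(g$wavelengths)))
  NextMethod()
}

#' Trim a spectra table to a wavelength range
#'
#' Sensor edges carry unstable reflectance; modeling uses an interior window
#' (430--900 nm for the VNIR lens, 950--1650 nm for the SWIR lens). Bands with
#' `min_nm <= lambda <= max_nm` are kept (boundaries inclusive, so the printed
#' endpoints stay in range); the retained original band indices are recorded
#' in the `trim_index` attribute.
#'
#' @param x A [spectra_tbl()].
#' @param min_nm,max_nm Inclusive wavelength bounds (nm).
#' @return A trimmed `spectra_tbl`.
#' @examples
#' s <- spectra_tbl(matrix(0.5, 2, 4), sensor_grid("VNIR", c(425, 430, 500, 905)))
#' spectra_wavelengths(trim_to_range(s, 430, 900)) # 430, 500
#' @export
trim_to_range <- function(x, min_nm, max_nm) {
  assert_that_(min_nm < max_nm, "`min_nm` must be below `max_nm`.")
  g <- spectra_grid(x)
  keep <- which(g$wavelengths >= min_nm & g$wavelengths <= max_nm)
  if (length(keep) == 0) {
    abort(sprintf("trim range [%g, %g] nm retains no band of sensor %s.",
                  min_nm, max_nm, g$sensor_id))
  }
  m <- spectra_matrix(x)[, keep, drop = FALSE]
  out <- spectra_tbl(m, sensor_grid(g$sensor_id, g$wavelengths[keep]),
                     sample_ids = x$sample_id)
  prev <- attr(x, "trim_index") %||% seq_len(g$n_bands)
  attr(out, "trim_index") <- prev[keep]
  out
}

#' Read and write spectra tables
#'
#' The on-disk dialect is a plain UTF-8 CSV: header `sample_id` followed by
#' wavelengths in nm printed to 3 decimals; one row per sample. Reading
#' validates the layout and reports the offending row/column on failure;
#' wavelengths must be strictly increasing.
#'
#' @param path File path.
#' @param sensor_id Sensor label to attach on read (default `"UNKNOWN"`).
#' @return `read_spectra_table()` returns a [spectra_tbl()];
#'   `write_spectra_table()` invisibly returns `path`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' s <- spectra_tbl(matrix(runif(6), 2), sensor_grid("SWIR", c(1000, 1100, 1200)))
#' write_spectra_table(s, f)
#' identical(spectra_matrix(read_spectra_table(f, "SWIR")), spectra_matrix(s))
#' @export
read_spectra_table <- function(path, sensor_id = "UNKNOWN") {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  assert_that_(length(lines) >= 2, "spectra table needs a header and at least one row.")
  cells <- strsplit(lines, ",", fixed = TRUE)
  header <- cells[[1]]
  assert_that_(header[1] == "sample_id",
               "first header cell must be 'sample_id'.")
  wl <- suppressWarnings(as.numeric(header[-1]))
  if (anyNA(wl)) {
    abort(sprintf("non-numeric wavelength in header column %d ('%s').",
                  which(is.na(wl))[1] + 1L, header[-1][which(is.na(wl))[1]]))
  }
  if (any(diff(wl) <= 0)) {
    abort(sprintf("wavelengths must be strictly increasing; violation at header column %d.",
                  which(diff(wl) <= 0)[1] + 2L))
  }
  n_col <- length(header)
  rows <- cells[-1]
  ids <- character(length(rows))
  m <- matrix(NA_real_, nrow = length(rows), ncol = n_col - 1L)
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (length(r) != n_col) {
      abort(sprintf("ragged row %d: expected %d cells, found %d.",
                    i + 1L, n_col, length(r)))
    }
    ids[i] <- r[1]
    v <- suppressWarnings(as.numeric(r[-1]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1]
      abort(sprintf("non-numeric cell at row %d, column %d ('%s').",
                    i + 1L, j + 1L, r[-1][j]))
    }
    m[i, ] <- v
  }
  spectra_tbl(m, sensor_grid(sensor_id, wl), sample_ids = ids)
}

#' @rdname read_spectra_table
#' @param x A [spectra_tbl()] to write.
#' @export
write_spectra_table <- function(x, path) {
  g <- spectra_grid(x)
  m <- spectra_matrix(x)
  header <- paste(c("sample_id", format_wl(g$wavelengths)), collapse = ",")
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(x$sample_id[i], format(m[i, ], digits = 15, trim = TRUE, scientific = FALSE)),
          collapse = ",")
  }, character(1))
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}
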