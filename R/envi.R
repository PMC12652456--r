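#' Hyperspectral cubes and ROI mean spectra
#'
#' A `hypercube` stores a lines x samples x bands reflectance array together
#' with its [sensor_grid()]. Cubes round-trip through the ENVI format
#' (`read_envi()` / `write_envi()`), the standard container written by
#' hyperspectral acquisition software; data types 4/5 (32/64-bit float) and
#' 12 (uint16 with a reflectance scale factor) and all three interleaves
#' (BSQ/BIL/BIP) are supported.
#'
#' @param values Numeric 3-d array, `lines x samples x bands`.
#' @param grid A [sensor_grid()] with `n_bands == dim(values)[3]`.
#' @return A `hypercube` object.
#' @export
hypercube <- function(values, grid) {
  assert_that_(is.array(values) && length(dim(values)) == 3,
               "`values` must be a 3-d array (lines x samples x bands).")
  assert_that_(inherits(grid, "sensor_grid"), "`grid` must be a sensor_grid.")
  assert_that_(dim(values)[3] == grid$n_bands,
               sprintf("cube has %d bands but grid has %d.",
                       dim(values)[3], grid$n_bands))
  storage.mode(values) <- "double"
  structure(list(values = values, grid = grid), class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<hypercube %s: %d lines x %d samples x %d bands>\n",
              x$grid$sensor_id, d[1], d[2], d[3]))
  invisible(x)
}

# interleave-specific permutation between array [lines, samples, bands] and
# the on-disk element order (first listed dimension varies fastest)
envi_perm <- function(interleave) {
  switch(toupper(interleave),
         BSQ = c(2, 1, 3),  # sample, line, band
         BIL = c(2, 3, 1),  # sample, band, line
         BIP = c(3, 2, 1),  # band, sample, line
         abort(sprintf("unsupported interleave '%s'.", interleave)))
}

#' Write a hypercube as an ENVI file pair
#'
#' @param cube A [hypercube()].
#' @param data_path Path for the binary payload; the header is written to
#'   `paste0(data_path, ".hdr")`.
#' @param interleave `"BSQ"`, `"BIL"` or `"BIP"`.
#' @param data_type ENVI data type code: 4 (float32), 5 (float64) or
#'   12 (uint16, stored as `round(reflectance * scale)`).
#' @param scale Reflectance scale factor used for data type 12.
#' @return Invisibly, the header path.
#' @export
write_envi <- function(cube, data_path, interleave = "BSQ", data_type = 4,
                       scale = 10000) {
  assert_that_(inherits(cube, "hypercube"), "`cube` must be a hypercube.")
  assert_that_(data_type %in% c(4, 5, 12),
               "only ENVI data types 4, 5 and 12 are supported.")
  d <- dim(cube$values)
  v <- as.vector(aperm(cube$values, envi_perm(interleave)))
  con <- file(data_path, "wb")
  on.exit(close(con), add = TRUE)
  if (data_type == 4) {
    writeBin(v, con, size = 4, endian = "little")
  } else if (data_type == 5) {
    writeBin(v, con, size = 8, endian = "little")
  } else {
    writeBin(as.integer(round(v * scale)), con, size = 2, endian = "little")
  }
  hdr <- c(
    "ENVI",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", data_type),
    sprintf("interleave = %s", tolower(interleave)),
    "byte order = 0",
    if (data_type == 12) sprintf("reflectance scale factor = %d", scale),
    sprintf("sensor type = %s", cube$grid$sensor_id),
    sprintf("wavelength = {%s}",
            paste(format_wl(cube$grid$wavelengths), collapse = ", "))
  )
  writeLines(hdr, paste0(data_path, ".hdr"))
  invisible(paste0(data_path, ".hdr"))
}

parse_envi_header <- function(header_path) {
  txt <- paste(readLines(header_path, warn = FALSE), collapse = "\n")
  assert_that_(grepl("^ENVI", txt), "not an ENVI header (missing ENVI magic).")
  fields <- list()
  # values in braces may span lines; normalise them first
  braced <- regmatches(txt, gregexpr("[a-z ]+=\\s*\\{[^}]*\\}", txt))[[1]]
  for (b in braced) {
    key <- trimws(sub("=.*", "", b))
    val <- sub(".*\\{", "", sub("\\}.*", "", b))
    fields[[key]] <- trimws(strsplit(val, ",")[[1]])
    txt <- sub(b, "", txt, fixed = TRUE)
  }
  for (line in strsplit(txt, "\n")[[1]]) {
    if (!grepl("=", line)) next
    key <- trimws(sub("=.*", "", line))
    fields[[key]] <- trimws(sub(".*?=", "", line))
  }
  fields
}

#' Read an ENVI file pair
#'
#' @param header_path Path to the `.hdr` text header.
#' @param data_path Path to the binary payload (default: header path without
#'   the `.hdr` suffix).
#' @return A [hypercube()]. Values are identical whichever interleave dialect
#'   the file uses.
#' @export
read_envi <- function(header_path, data_path = sub("\\.hdr$", "", header_path)) {
  h <- parse_envi_header(header_path)
  need <- c("samples", "lines", "bands", "data type", "interleave")
  missing <- setdiff(need, names(h))
  assert_that_(length(missing) == 0,
               sprintf("ENVI header missing field(s): %s.",
                       paste(missing, collapse = ", ")))
  ns <- as.integer(h[["samples"]]); nl <- as.integer(h[["lines"]])
  nb <- as.integer(h[["bands"]])
  dt <- as.integer(h[["data type"]])
  interleave <- toupper(h[["interleave"]])
  endian <- if (!is.null(h[["byte order"]]) && h[["byte order"]] == "1") "big" else "little"
  n <- ns * nl * nb
  con <- file(data_path, "rb")
  on.exit(close(con), add = TRUE)
  payload_bytes <- file.size(data_path)
  elt_size <- switch(as.character(dt), "4" = 4L, "5" = 8L, "12" = 2L,
                     abort(sprintf("unsupported ENVI data type %d (supported: 4, 5, 12).", dt)))
  if (payload_bytes != n * elt_size) {
    abort(sprintf(
      "ENVI size mismatch: header implies %d bytes (%d x %d x %d x %d) but payload has %d.",
      n * elt_size, nl, ns, nb, elt_size, payload_bytes))
  }
  v <- if (dt == 4) {
    readBin(con, "double", n = n, size = 4, endian = endian)
  } else if (dt == 5) {
    readBin(con, "double", n = n, size = 8, endian = endian)
  } else {
    scale <- as.numeric(h[["reflectance scale factor"]] %||% 10000)
    readBin(con, "integer", n = n, size = 2, signed = FALSE, endian = endian) / scale
  }
  perm <- envi_perm(interleave)
  dims <- c(nl, ns, nb)[perm]
  arr <- aperm(array(v, dim = dims), order(perm))
  wl <- if (!is.null(h[["wavelength"]])) as.numeric(h[["wavelength"]]) else seq_len(nb)
  sensor <- h[["sensor type"]] %||% "UNKNOWN"
  hypercube(arr, sensor_grid(sensor, wl))
}

#' ROI mean reflectance
#'
#' Collapses a hypercube to one sample spectrum by averaging reflectance over
#' the pixels of a region of interest: per band, `R = (1/n) * sum(R_i)` over
#' the `n` selected pixels.
#'
#' @param cube A [hypercube()].
#' @param roi Logical lines x samples matrix marking ROI pixels; must select
#'   at least one pixel. Defaults to the full frame.
#' @return Named numeric vector (one mean reflectance per band).
#' @examples
#' cube <- hypercube(array(0.3, c(2, 2, 3)), sensor_grid("SWIR", c(1000, 1100, 1200)))
#' mean_reflectance(cube)
#' @export
mean_reflectance <- function(cube, roi = NULL) {
  assert_that_(inherits(cube, "hypercube"), "`cube` must be a hypercube.")
  d <- dim(cube$values)
  if (is.null(roi)) roi <- matrix(TRUE, d[1], d[2])
  assert_that_(is.logical(roi) && all(dim(roi) == d[1:2]),
               "`roi` must be a logical lines x samples matrix matching the cube.")
  assert_that_(any(roi), "ROI mask selects no pixel.")
  flat <- cube$values
  dim(flat) <- c(d[1] * d[2], d[3])
  out <- colMeans(flat[as.vector(roi), , drop = FALSE])
  names(out) <- format_wl(cube$grid$wavelengths)
  out
}
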