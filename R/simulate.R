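#' Default planted absorption features
#'
#' The generator plants Gaussian absorption features at the landmark
#' wavelengths where sorghum spectra respond to tannin (chromophore bands in
#' the visible, C-H/N-H related bands in the SWIR) and to moisture (O-H
#' bands). Depth of band *k* for a sample with tannin `T` (%) and moisture
#' `M` (%) is
#' `depth_k = linear_depth * T + quadratic_depth * T^2` for tannin bands,
#' `linear_depth * M` for moisture bands, and `linear_depth * T * M` for the
#' tannin-moisture cross band. Centres/widths in nm; depths in reflectance
#' units per % (or %^2).
#'
#' @return A tibble with columns `sensor`, `center`, `width`, `linear_depth`,
#'   `quadratic_depth`, `driver`.
#' @export
default_feature_bands <- function() {
  tibble::tribble(
    ~sensor, ~center, ~width, ~linear_depth, ~quadratic_depth, ~driver,
    "VNIR",  530,     12,     0.012,         0.0018,           "tannin",
    "VNIR",  580,     12,     0.010,         0.0015,           "tannin",
    "VNIR",  650,     12,     0.014,         0.0021,           "tannin",
    "VNIR",  670,     14,     0.020,         0.0030,           "tannin",
    "VNIR",  845,     16,     0.006,         0.0009,           "tannin",
    "VNIR",  890,     16,     0.006,         0.0009,           "tannin",
    "SWIR",  1130,    22,     0.010,         0.0015,           "tannin",
    "SWIR",  1558,    24,     0.012,         0.0018,           "tannin",
    "SWIR",  1402,    26,     0.010,         0,                "moisture",
    "SWIR",  1480,    30,     0.010,         0,                "moisture",
    "SWIR",  1130,    22,     0.0050,        0,                "cross",
    "SWIR",  1558,    24,     0.0050,        0,                "cross"
  )
}

#' Generator parameters
#'
#' Parameters of the synthetic dual-sensor study generator. Defaults
#' reproduce the study design: 240 samples whose tannin reference values
#' have mean 1.18 %, SD 0.7320 % and range 0.05--2.56 %, with
#' tannin-dependent absorption planted at the landmark wavelengths of
#' [default_feature_bands()], a moisture nuisance partially correlated with
#' tannin, per-sample multiplicative/additive scatter, and white noise.
#'
#' @param n_samples Number of samples (default 240).
#' @param tannin_mean,tannin_sd Target mean and SD of the tannin reference
#'   values (%).
#' @param tannin_bounds Length-2 inclusive range (%) for the truncated-normal
#'   tannin draw.
#' @param feature_bands Planted bands, see [default_feature_bands()].
#' @param moisture_mean,moisture_sd Moisture distribution (%).
#' @param moisture_tannin_corr Correlation between moisture and tannin
#'   (default 0.3, a mild nuisance coupling).
#' @param scatter_slope_sd,scatter_offset_sd Per-sample multiplicative and
#'   additive scatter SDs (unitless / reflectance units).
#' @param noise_sd Additive white-noise SD (reflectance units).
#' @param assay_error_sd SD (% tannin) of the reference-assay error: spectra
#'   are driven by the sample's latent chemical tannin, while the recorded
#'   reference value deviates from it by this much (wet-chemistry
#'   spectrophotometric assays carry relative errors of roughly 5--15 %).
#'   This, not detector noise, is what bounds attainable prediction accuracy
#'   at realistic levels; set to 0 for noise-free identities.
#' @param seed Integer seed; every draw is reproducible under a fixed seed.
#' @return A validated `generator_params` list.
#' @export
generator_params <- function(n_samples = 240,
                             tannin_mean = 1.18,
                             tannin_sd = 0.7320,
                             tannin_bounds = c(0.05, 2.56),
                             feature_bands = default_feature_bands(),
                             moisture_mean = 10,
                             moisture_sd = 2,
                             moisture_tannin_corr = 0.3,
                             scatter_slope_sd = 0.06,
                             scatter_offset_sd = 0.02,
                             noise_sd = 0.008,
                             assay_error_sd = 0.25,
                             seed = NULL) {
  p <- list(n_samples = n_samples, tannin_mean = tannin_mean,
            tannin_sd = tannin_sd, tannin_bounds = as.numeric(tannin_bounds),
            feature_bands = feature_bands,
            moisture_mean = moisture_mean, moisture_sd = moisture_sd,
            moisture_tannin_corr = moisture_tannin_corr,
            scatter_slope_sd = scatter_slope_sd,
            scatter_offset_sd = scatter_offset_sd,
            noise_sd = noise_sd, assay_error_sd = assay_error_sd, seed = seed)
  validate_generator_params(p)
  structure(p, class = "generator_params")
}

validate_generator_params <- function(p) {
  assert_that_(is_count(p$n_samples) && p$n_samples >= 1,
               "`n_samples` must be a positive count.")
  assert_that_(length(p$tannin_bounds) == 2 &&
                 p$tannin_bounds[1] < p$tannin_bounds[2],
               "`tannin_bounds` must be an ordered pair.")
  assert_that_(p$tannin_mean > p$tannin_bounds[1] &&
                 p$tannin_mean < p$tannin_bounds[2],
               "`tannin_mean` must lie strictly inside `tannin_bounds`.")
  for (f in c("tannin_sd", "moisture_sd", "scatter_slope_sd",
              "scatter_offset_sd", "noise_sd", "assay_error_sd")) {
    assert_that_(is.numeric(p[[f]]) && p[[f]] >= 0,
                 sprintf("`%s` must be >= 0.", f))
  }
  assert_that_(abs(p$moisture_tannin_corr) <= 1,
               "`moisture_tannin_corr` must be in [-1, 1].")
  fb <- p$feature_bands
  assert_that_(all(c("sensor", "center", "width", "linear_depth",
                     "quadratic_depth", "driver") %in% names(fb)),
               "`feature_bands` is missing required columns.")
  rng <- list(VNIR = range(vnir_grid()$wavelengths),
              SWIR = range(swir_grid()$wavelengths))
  for (i in seq_len(nrow(fb))) {
    s <- fb$sensor[i]
    if (s %in% names(rng)) {
      assert_that_(fb$center[i] >= rng[[s]][1] && fb$center[i] <= rng[[s]][2],
                   sprintf("feature band %.0f nm lies outside the %s range.",
                           fb$center[i], s))
    }
  }
  invisible(TRUE)
}

# closed-form moments of a normal(mu, s) truncated to [a, b]
truncnorm_moments <- function(mu, s, a, b) {
  al <- (a - mu) / s; be <- (b - mu) / s
  Z <- pnorm(be) - pnorm(al)
  m <- mu + s * (dnorm(al) - dnorm(be)) / Z
  v <- s^2 * (1 + (al * dnorm(al) - be * dnorm(be)) / Z -
                ((dnorm(al) - dnorm(be)) / Z)^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# parent (mu0, s0) whose truncation to [a, b] best matches the target
# mean/sd (least squares on the closed-form truncated moments). A truncated
# distribution's SD is capped below (b-a)/sqrt(12)-ish, so an exact match may
# be unattainable; the closest attainable pair is used.
match_truncnorm <- function(mean, sd, a, b) {
  obj <- function(par) {
    m <- truncnorm_moments(par[1], exp(par[2]), a, b)
    (m[["mean"]] - mean)^2 + (m[["sd"]] - sd)^2
  }
  span <- b - a
  o <- stats::optim(c(mean, log(sd)), obj, method = "L-BFGS-B",
                    lower = c(a - 60 * span, log(sd / 20)),
                    upper = c(b + 60 * span, log(20 * span)),
                    control = list(maxit = 500))
  list(mu = o$par[1], sd = exp(o$par[2]))
}

# Inverse-CDF truncated-normal sampler, tail-stable for extreme parents.
# The uniforms are stratified (one randomized draw per probability stratum,
# order shuffled): each value is still marginally truncated-normal and the
# vector is exchangeable, but the empirical distribution — and hence the
# sample mean/SD the generator is asked to emulate — tracks the target
# closely under every seed instead of only on average.
rtruncnorm_ <- function(n, mu, s, a, b) {
  al <- (a - mu) / s; be <- (b - mu) / s
  u <- sample((seq_len(n) - stats::runif(n)) / n)
  if (al > 0) { # both bounds in the upper tail: work with survival function
    qa <- pnorm(al, lower.tail = FALSE)
    qb <- pnorm(be, lower.tail = FALSE)
    z <- stats::qnorm(qa - u * (qa - qb), lower.tail = FALSE)
  } else if (be < 0) {
    pa <- pnorm(al); pb <- pnorm(be)
    z <- stats::qnorm(pa + u * (pb - pa))
  } else {
    pa <- pnorm(al); pb <- pnorm(be)
    z <- stats::qnorm(pa + u * (pb - pa))
  }
  pmin(pmax(mu + s * z, a), b)
}

#' Generate synthetic tannin reference values
#'
#' Draws `n_samples` tannin contents (%) from a truncated normal on
#' `tannin_bounds`. The parent parameters are moment-matched numerically so
#' the *truncated* distribution's mean and SD sit as close as attainable to
#' `tannin_mean` / `tannin_sd` (naive truncation of a normal with those
#' parameters would shrink the SD well below the target), and the draw uses
#' stratified inverse-CDF sampling so the sample moments track those targets
#' under every seed, not just in expectation.
#'
#' @param params A [generator_params()].
#' @param seed Optional seed overriding `params$seed`.
#' @return Numeric vector of tannin contents (%), inside `tannin_bounds`.
#' @examples
#' t <- generate_tannin(generator_params(seed = 1))
#' round(c(mean(t), sd(t)), 2)
#' @export
generate_tannin <- function(params = generator_params(), seed = NULL) {
  validate_generator_params(params)
  seed <- seed %||% params$seed
  a <- params$tannin_bounds[1]; b <- params$tannin_bounds[2]
  if (params$tannin_sd == 0) {
    return(rep(params$tannin_mean, params$n_samples))
  }
  fit <- match_truncnorm(params$tannin_mean, params$tannin_sd, a, b)
  with_seed_(seed, rtruncnorm_(params$n_samples, fit$mu, fit$sd, a, b))
}

#' Smooth sensor baselines
#'
#' The noise- and feature-free reflectance curve of each sensor: the VNIR
#' baseline rises through the red edge (sigmoid around 715 nm); the SWIR
#' baseline is a gently sloping shelf with a broad depression around 1480 nm.
#' These shapes are configuration for the generator, not physical claims.
#'
#' @param wavelengths Numeric wavelengths (nm).
#' @param sensor `"VNIR"` or `"SWIR"`.
#' @return Numeric baseline reflectance, same length as `wavelengths`.
#' @export
sensor_baseline <- function(wavelengths, sensor = c("VNIR", "SWIR")) {
  sensor <- match.arg(sensor)
  if (sensor == "VNIR") {
    0.25 + 0.30 / (1 + exp(-(wavelengths - 715) / 18)) +
      2e-5 * (wavelengths - 430)
  } else {
    0.55 + 2e-5 * (wavelengths - 950) -
      0.18 * exp(-0.5 * ((wavelengths - 1480) / 90)^2) -
      0.04 * exp(-0.5 * ((wavelengths - 1200) / 60)^2)
  }
}

band_depths <- function(fb, tannin, moisture) {
  # samples x planted-bands matrix of absorption depths
  vapply(seq_len(nrow(fb)), function(k) {
    switch(fb$driver[k],
           tannin   = fb$linear_depth[k] * tannin +
                      fb$quadratic_depth[k] * tannin^2,
           moisture = fb$linear_depth[k] * moisture +
                      fb$quadratic_depth[k] * moisture^2,
           cross    = fb$linear_depth[k] * tannin * moisture,
           abort(sprintf("unknown feature-band driver '%s'.", fb$driver[k])))
  }, numeric(length(tannin)))
}

simulate_sensor_block <- function(grid, fb, tannin, moisture, params, seed) {
  n <- length(tannin)
  wl <- grid$wavelengths
  base <- sensor_baseline(wl, grid$sensor_id)
  fb_s <- fb[fb$sensor == grid$sensor_id, , drop = FALSE]
  spectra <- matrix(rep(base, each = n), nrow = n)
  if (nrow(fb_s) > 0) {
    depths <- band_depths(fb_s, tannin, moisture)  # n x k
    if (is.null(dim(depths))) depths <- matrix(depths, nrow = n)
    shapes <- vapply(seq_len(nrow(fb_s)), function(k) {
      exp(-0.5 * ((wl - fb_s$center[k]) / fb_s$width[k])^2)
    }, numeric(length(wl)))  # p x k
    spectra <- spectra - depths %*% t(shapes)
  }
  with_seed_(seed, {
    slope <- stats::rnorm(n, 0, params$scatter_slope_sd)
    offset <- stats::rnorm(n, 0, params$scatter_offset_sd)
    noise <- if (params$noise_sd > 0) {
      matrix(stats::rnorm(n * length(wl), 0, params$noise_sd), nrow = n)
    } else 0
    spectra <- spectra * (1 + slope) + offset + noise
  })
  pmin(pmax(spectra, 0), 1)
}

#' Generate a synthetic dual-sensor sample set
#'
#' Builds the full study data structure: tannin and moisture reference values
#' plus one reflectance spectrum per sample per sensor. Each spectrum is
#' `baseline * (1 + slope_i) + offset_i - sum_k depth_k * Gaussian(center_k,
#' width_k) + noise`, clipped to \[0, 1\]; depths depend on the sample's
#' tannin/moisture as described in [default_feature_bands()].
#'
#' @param params A [generator_params()].
#' @param grids List with elements `vnir` and `swir` ([sensor_grid()]s).
#' @param seed Optional seed overriding `params$seed`.
#' @return A `sample_set`: list with `reference` (tibble: `sample_id`,
#'   `tannin`, `moisture`), `vnir` and `swir` ([spectra_tbl()]s).
#' @examples
#' ss <- generate_sample_set(generator_params(n_samples = 5, seed = 7))
#' ss$reference
#' @export
generate_sample_set <- function(params = generator_params(),
                                grids = list(vnir = vnir_grid(),
                                             swir = swir_grid()),
                                seed = NULL) {
  validate_generator_params(params)
  seed <- seed %||% params$seed
  tannin <- generate_tannin(params, seed = derive_seed(seed, "tannin"))
  n <- params$n_samples
  moisture <- with_seed_(derive_seed(seed, "moisture"), {
    r <- params$moisture_tannin_corr
    zt <- if (isTRUE(stats::sd(tannin) > 0)) {
      (tannin - mean(tannin)) / stats::sd(tannin)
    } else rep(0, n)
    zm <- stats::rnorm(n)
    pmax(params$moisture_mean +
           params$moisture_sd * (r * zt + sqrt(1 - r^2) * zm), 0)
  })
  ids <- sprintf("S%03d", seq_len(n))
  # spectra respond to the latent chemical tannin; the recorded reference
  # deviates from it by the assay error, as a wet-chemistry reference does
  chem_tannin <- with_seed_(derive_seed(seed, "assay"), {
    pmax(tannin + stats::rnorm(n, 0, params$assay_error_sd), 0)
  })
  vnir <- simulate_sensor_block(grids$vnir, params$feature_bands, chem_tannin,
                                moisture, params, derive_seed(seed, "vnir"))
  swir <- simulate_sensor_block(grids$swir, params$feature_bands, chem_tannin,
                                moisture, params, derive_seed(seed, "swir"))
  structure(
    list(reference = tibble::tibble(sample_id = ids, tannin = tannin,
                                    moisture = moisture),
         vnir = spectra_tbl(vnir, grids$vnir, ids),
         swir = spectra_tbl(swir, grids$swir, ids)),
    class = "sample_set"
  )
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("<sample_set: %d samples; VNIR %d bands; SWIR %d bands>\n",
              nrow(x$reference), spectra_grid(x$vnir)$n_bands,
              spectra_grid(x$swir)$n_bands))
  cat(sprintf("  tannin: mean %.3f%%, sd %.3f%%, range [%.2f, %.2f]\n",
              mean(x$reference$tannin), stats::sd(x$reference$tannin),
              min(x$reference$tannin), max(x$reference$tannin)))
  invisible(x)
}

#' Generate a pixel-level hypercube for one sample
#'
#' Expands one sample's spectrum into a rectangular hypercube of `n_pixels`
#' pixels, each the sample spectrum plus independent pixel noise; the
#' ROI-mean spectrum converges to the sample spectrum as pixels accumulate.
#'
#' @param sample_set A [generate_sample_set()] result.
#' @param sensor `"vnir"` or `"swir"` block to expand.
#' @param sample_index Row index of the sample.
#' @param n_pixels Number of pixels (the study's ROIs exceed 16,000; default
#'   1,000 keeps desk-scale runs light).
#' @param pixel_noise_sd Independent per-pixel noise SD (reflectance units).
#' @param seed Optional seed.
#' @return A [hypercube()] whose lines x samples layout factors `n_pixels`.
#' @export
generate_hypercube <- function(sample_set, sensor = c("vnir", "swir"),
                               sample_index = 1, n_pixels = 1000,
                               pixel_noise_sd = 0.01, seed = NULL) {
  sensor <- match.arg(sensor)
  assert_that_(is_count(n_pixels) && n_pixels >= 1,
               "`n_pixels` must be a positive count.")
  block <- sample_set[[sensor]]
  assert_that_(is_count(sample_index) && sample_index >= 1 &&
                 sample_index <= nrow(block),
               "`sample_index` out of range.")
  grid <- spectra_grid(block)
  spec <- spectra_matrix(block)[sample_index, ]
  lines <- max(1L, floor(sqrt(n_pixels)))
  while (n_pixels %% lines != 0) lines <- lines - 1L
  samples <- n_pixels %/% lines
  p <- grid$n_bands
  vals <- with_seed_(seed, {
    noise <- if (pixel_noise_sd > 0) {
      matrix(stats::rnorm(n_pixels * p, 0, pixel_noise_sd), nrow = n_pixels)
    } else 0
    matrix(rep(spec, each = n_pixels), nrow = n_pixels) + noise
  })
  vals <- pmin(pmax(vals, 0), 1)
  hypercube(array(vals, dim = c(lines, samples, p)), grid)
}
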