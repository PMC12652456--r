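# Shared fixtures, all generated in code.

# Reduced wavelength grids spanning the full sensor ranges: every planted
# feature band stays in range while pipelines run fast.
tiny_grids <- function(n_vnir = 80, n_swir = 40) {
  list(vnir = sensor_grid("VNIR", seq(430, 900, length.out = n_vnir)),
       swir = sensor_grid("SWIR", seq(950, 1650, length.out = n_swir)))
}

small_sample_set <- function(n = 60, seed = 1, ...) {
  generate_sample_set(generator_params(n_samples = n, seed = seed, ...),
                      grids = tiny_grids())
}

# Linear planted-signal regression data: k informative columns out of p.
planted_data <- function(n, p, informative, noise_sd = 0.3, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n)
    beta <- numeric(p)
    beta[informative] <- 1
    list(X = X, y = as.vector(X %*% beta + rnorm(n, 0, noise_sd)),
         informative = informative)
  })
}

fast_cars <- function(seed = 1) {
  cars_config(n_mc_runs = 20, stability_repeats = 2, seed = seed)
}
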