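#' Experiment configuration
#'
#' Assembles everything [run_experiment()] needs: the data source (generator
#' parameters, or paths to per-sensor spectra tables plus a reference CSV),
#' split and fold settings, the CARS configuration, model specifications, the
#' replication count feeding the ANOVA model comparison, and a global seed
#' that deterministically drives every stage.
#'
#' @param generator [generator_params()] for synthetic data (ignored when
#'   file paths are given).
#' @param vnir_path,swir_path,reference_path Optional paths: spectra-table
#'   CSVs ([read_spectra_table()]) and a reference CSV with columns
#'   `sample_id`, `tannin`.
#' @param split_fraction Calibration fraction (default 0.75).
#' @param cv_folds Folds for all tuning (default 5).
#' @param cars CARS settings ([cars_config()]).
#' @param svr SVR settings ([svr_spec()]).
#' @param cnn CNN settings ([cnn_spec()]).
#' @param families Model families to fit (subset of `"pls"`, `"svr"`,
#'   `"cnn"`).
#' @param variants Dataset variants to build (subset of the six standard
#'   ones: `"VNIR-Raw"`, `"SWIR-Raw"`, `"Whole-Raw"`, `"VNIR-Feature"`,
#'   `"SWIR-Feature"`, `"Fused-Feature"`).
#' @param anova_replicates Repeated seeded hold-out splits used to produce
#'   per-family RMSEP replicates for the ANOVA comparison (default 10; 0
#'   disables the comparison).
#' @param anova_variant Variant on which the replicated comparison runs
#'   (default `"Fused-Feature"`).
#' @param seed Global integer seed.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(generator = generator_params(),
                              vnir_path = NULL, swir_path = NULL,
                              reference_path = NULL,
                              split_fraction = 0.75,
                              cv_folds = 5,
                              cars = cars_config(),
                              svr = svr_spec(),
                              cnn = cnn_spec(),
                              families = c("pls", "svr", "cnn"),
                              variants = c("VNIR-Raw", "SWIR-Raw", "Whole-Raw",
                                           "VNIR-Feature", "SWIR-Feature",
                                           "Fused-Feature"),
                              anova_replicates = 10,
                              anova_variant = "Fused-Feature",
                              seed = 1L) {
  families <- match.arg(families, c("pls", "svr", "cnn"), several.ok = TRUE)
  known <- c("VNIR-Raw", "SWIR-Raw", "Whole-Raw",
             "VNIR-Feature", "SWIR-Feature", "Fused-Feature")
  assert_that_(all(variants %in% known),
               sprintf("unknown variant(s): %s.",
                       paste(setdiff(variants, known), collapse = ", ")))
  paths <- c(vnir_path, swir_path, reference_path)
  if (length(paths) > 0) {
    missing <- paths[!file.exists(paths)]
    assert_that_(length(missing) == 0,
                 sprintf("input file(s) not found: %s.",
                         paste(missing, collapse = ", ")))
  }
  structure(list(generator = generator, vnir_path = vnir_path,
                 swir_path = swir_path, reference_path = reference_path,
                 split_fraction = split_fraction, cv_folds = cv_folds,
                 cars = cars, svr = svr, cnn = cnn, families = families,
                 variants = variants, anova_replicates = anova_replicates,
                 anova_variant = anova_variant, seed = as.integer(seed)),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML or JSON
#'
#' Keys mirror the arguments of [experiment_config()], [generator_params()],
#' [cars_config()], [svr_spec()] and [cnn_spec()]; unknown keys raise an
#' error. Nested sections `generator`, `cars`, `svr` and `cnn` override the
#' respective defaults field by field.
#'
#' @param path A `.yaml`/`.yml` or `.json` file.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  build_section <- function(fn, values) {
    if (is.null(values)) return(fn())
    bad <- setdiff(names(values), names(formals(fn)))
    assert_that_(length(bad) == 0,
                 sprintf("unknown config key(s): %s.", paste(bad, collapse = ", ")))
    do.call(fn, values)
  }
  args <- raw
  args$generator <- build_section(generator_params, raw$generator)
  args$cars <- build_section(cars_config, raw$cars)
  args$svr <- build_section(svr_spec, raw$svr)
  args$cnn <- build_section(cnn_spec, raw$cnn)
  bad <- setdiff(names(args), names(formals(experiment_config)))
  assert_that_(length(bad) == 0,
               sprintf("unknown config key(s): %s.", paste(bad, collapse = ", ")))
  do.call(experiment_config, args)
}

load_experiment_data <- function(config) {
  if (!is.null(config$vnir_path)) {
    vnir <- read_spectra_table(config$vnir_path, "VNIR")
    swir <- read_spectra_table(config$swir_path, "SWIR")
    ref <- utils::read.csv(config$reference_path, stringsAsFactors = FALSE)
    assert_that_(all(c("sample_id", "tannin") %in% names(ref)),
                 "reference CSV needs `sample_id` and `tannin` columns.")
    assert_that_(identical(as.character(ref$sample_id), vnir$sample_id) &&
                   identical(vnir$sample_id, swir$sample_id),
                 "sample ids of the two sensors and the reference disagree.")
    list(vnir = vnir, swir = swir,
         reference = tibble::as_tibble(ref))
  } else {
    generate_sample_set(config$generator,
                        seed = derive_seed(config$seed, "generate"))
  }
}

fit_family <- function(family, X, y, config, folds, seed) {
  switch(family,
         pls = fit_pls(X, y, folds, config$cars$max_pls_components),
         svr = tune_fit_svr(X, y, config$svr, folds),
         cnn = fit_cnn(X, y, config$cnn, seed = seed),
         abort(sprintf("unknown model family '%s'.", family)))
}

subset_rows <- function(tbl, idx) {
  out <- spectra_tbl(spectra_matrix(tbl)[idx, , drop = FALSE],
                     spectra_grid(tbl), sample_ids = tbl$sample_id[idx])
  attr(out, "selected_index") <- attr(tbl, "selected_index")
  out
}

build_variants <- function(vnir, swir, cars_vnir, cars_swir, variants) {
  out <- list()
  if ("VNIR-Raw" %in% variants) out[["VNIR-Raw"]] <- vnir
  if ("SWIR-Raw" %in% variants) out[["SWIR-Raw"]] <- swir
  if ("Whole-Raw" %in% variants) out[["Whole-Raw"]] <- concat_data_layer(vnir, swir)
  needs_vf <- any(c("VNIR-Feature", "Fused-Feature") %in% variants)
  needs_sf <- any(c("SWIR-Feature", "Fused-Feature") %in% variants)
  vf <- if (needs_vf) apply_selection(vnir, cars_vnir)
  sf <- if (needs_sf) apply_selection(swir, cars_swir)
  if ("VNIR-Feature" %in% variants) out[["VNIR-Feature"]] <- vf
  if ("SWIR-Feature" %in% variants) out[["SWIR-Feature"]] <- sf
  if ("Fused-Feature" %in% variants) out[["Fused-Feature"]] <- concat_feature_layer(vf, sf)
  out[variants[variants %in% names(out)]]
}

#' Run the full dual-sensor experiment
#'
#' Orchestrates the whole study on one dataset: generate or load the data,
#' hold out a prediction set, select wavelengths with CARS per sensor on
#' calibration rows only, build the requested dataset variants (raw and
#' feature, single-sensor and fused), tune and fit the requested model
#' families on calibration data with shared stratified folds, evaluate each
#' model on the calibration and the untouched prediction partitions, and —
#' when `anova_replicates > 0` — re-run the chosen variant across repeated
#' seeded hold-out splits to feed the ANOVA + Tukey HSD family comparison.
#' Tuning never sees prediction-set rows.
#'
#' @param config An [experiment_config()].
#' @param verbose Print per-stage progress (default `FALSE`).
#' @return A `tannin_experiment`: list with `metrics` (tibble: variant,
#'   family, partition metrics), `cars` (per-sensor [select_features()]
#'   results), `models`, `split`, `comparison` (or `NULL`), `residuals`
#'   (prediction-set residual tables), `config`.
#' @export
run_experiment <- function(config = experiment_config(), verbose = FALSE) {
  assert_that_(inherits(config, "experiment_config"),
               "`config` must come from experiment_config().")
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  data <- load_experiment_data(config)
  y_all <- data$reference$tannin
  n <- length(y_all)
  say("data: %d samples [%.1fs]", n, as.numeric(Sys.time() - t0, units = "secs"))

  split <- holdout_split(n, config$split_fraction,
                         seed = derive_seed(config$seed, "split"))
  cal <- split$calibration; prd <- split$prediction
  y_cal <- y_all[cal]; y_prd <- y_all[prd]
  folds <- stratified_kfold(y_cal, k = config$cv_folds,
                            seed = derive_seed(config$seed, "folds"))

  needs_cars <- any(grepl("Feature", config$variants))
  cars_vnir <- cars_swir <- NULL
  if (needs_cars) {
    cars_vnir <- select_features(subset_rows(data$vnir, cal), y_cal, config$cars,
                                 seed = derive_seed(config$seed, "cars_vnir"))
    say("CARS VNIR: %d bands [%.1fs]", length(cars_vnir$selected),
        as.numeric(Sys.time() - t0, units = "secs"))
    cars_swir <- select_features(subset_rows(data$swir, cal), y_cal, config$cars,
                                 seed = derive_seed(config$seed, "cars_swir"))
    say("CARS SWIR: %d bands [%.1fs]", length(cars_swir$selected),
        as.numeric(Sys.time() - t0, units = "secs"))
  }
  # selection happened on calibration rows; rebuild variants on all rows so
  # prediction rows travel through identical columns
  variants_all <- build_variants(data$vnir, data$swir, cars_vnir, cars_swir,
                                 config$variants)

  models <- list(); metrics <- list(); residuals <- list()
  for (v in names(variants_all)) {
    Xv <- spectra_matrix(variants_all[[v]])
    for (fam in config$families) {
      m <- fit_family(fam, Xv[cal, , drop = FALSE], y_cal, config, folds,
                      seed = derive_seed(config$seed, paste0("fit_", v), match(fam, config$families)))
      key <- paste(v, fam, sep = "/")
      models[[key]] <- m
      pred_cal <- predict(m, Xv[cal, , drop = FALSE])
      pred_prd <- predict(m, Xv[prd, , drop = FALSE])
      metrics[[key]] <- dplyr::bind_rows(
        metrics_report(tibble::tibble(tannin = y_cal, .pred = pred_cal),
                       set = "calibration"),
        metrics_report(tibble::tibble(tannin = y_prd, .pred = pred_prd),
                       set = "prediction")) |>
        dplyr::mutate(variant = v, family = fam,
                      n_features = ncol(Xv), .before = 1)
      residuals[[key]] <- tibble::tibble(
        variant = v, family = fam, sample_id = data$reference$sample_id[prd],
        reference = y_prd, predicted = pred_prd,
        residual = pred_prd - y_prd)
      say("model %s: prediction R2 %.3f [%.1fs]", key,
          metrics[[key]]$r2[metrics[[key]]$set == "prediction"],
          as.numeric(Sys.time() - t0, units = "secs"))
    }
  }

  comparison <- NULL
  replicate_rmsep <- NULL
  if (config$anova_replicates >= 2 && length(config$families) >= 2) {
    av <- config$anova_variant
    assert_that_(av %in% names(variants_all),
                 sprintf("anova_variant '%s' is not among the built variants.", av))
    Xv <- spectra_matrix(variants_all[[av]])
    replicate_rmsep <- purrr::map_dfr(seq_len(config$anova_replicates), function(r) {
      sp <- holdout_split(n, config$split_fraction,
                          seed = derive_seed(config$seed, "anova_split", r))
      yc <- y_all[sp$calibration]; yp <- y_all[sp$prediction]
      fds <- stratified_kfold(yc, k = config$cv_folds,
                              seed = derive_seed(config$seed, "anova_folds", r))
      purrr::map_dfr(config$families, function(fam) {
        m <- fit_family(fam, Xv[sp$calibration, , drop = FALSE], yc, config, fds,
                        seed = derive_seed(config$seed, paste0("anova_", fam), r))
        tibble::tibble(replicate = r, family = fam,
                       rmsep = rmse(yp, predict(m, Xv[sp$prediction, , drop = FALSE])))
      })
    })
    comparison <- compare_models_anova(replicate_rmsep, "family", "rmsep")
    say("ANOVA: F(%d, %d) = %.2f [%.1fs]", comparison$anova$df1,
        comparison$anova$df2, comparison$anova$f,
        as.numeric(Sys.time() - t0, units = "secs"))
  }

  structure(list(metrics = dplyr::bind_rows(metrics),
                 cars = list(vnir = cars_vnir, swir = cars_swir),
                 models = models, split = split,
                 comparison = comparison,
                 replicate_rmsep = replicate_rmsep,
                 residuals = dplyr::bind_rows(residuals),
                 config = config),
            class = "tannin_experiment")
}

#' @export
print.tannin_experiment <- function(x, ...) {
  cat(sprintf("<tannin_experiment: %d models over %d variants>\n",
              length(x$models), length(unique(x$metrics$variant))))
  print(x$metrics |>
          dplyr::filter(.data$set == "prediction") |>
          dplyr::select("variant", "family", "n_features", "r2", "rmse", "rpd"))
  invisible(x)
}

#' @rdname tidy.tannin_model
#' @export
tidy.tannin_experiment <- function(x, ...) x$metrics

#' @rdname tidy.tannin_model
#' @export
glance.tannin_experiment <- function(x, ...) {
  pred <- dplyr::filter(x$metrics, .data$set == "prediction")
  best <- pred[which.max(pred$r2), ]
  tibble::tibble(n_models = length(x$models),
                 n_variants = length(unique(x$metrics$variant)),
                 best_variant = best$variant, best_family = best$family,
                 best_r2 = best$r2, best_rmse = best$rmse, best_rpd = best$rpd)
}

#' Radar-style metric export
#'
#' The per-model metric table in tidy long form (model x partition x metric),
#' the layout radar charts are drawn from.
#'
#' @param experiment A [run_experiment()] result.
#' @return Tibble with `variant`, `family`, `set`, `metric`, `value`.
#' @export
radar_data <- function(experiment) {
  experiment$metrics |>
    dplyr::select("variant", "family", "set", "r2", "rmse", "rpd") |>
    tidyr::pivot_longer(c("r2", "rmse", "rpd"),
                        names_to = "metric", values_to = "value")
}

#' ANOVA comparison from replicate errors
#'
#' Thin delegate to [compare_models_anova()] for a replicate table produced
#' by [run_experiment()] (or assembled by hand).
#'
#' @param replicates Data frame with columns `family` and `rmsep`.
#' @return A `comparison_report`.
#' @export
make_comparison <- function(replicates) {
  compare_models_anova(replicates, "family", "rmsep")
}
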