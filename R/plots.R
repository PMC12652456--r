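#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_histogram geom_hline facet_wrap facet_grid labs theme_minimal vars
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot methods
#'
#' `autoplot()` methods for the main result types: the mean spectra of a
#' sample set, the RMSECV / retained-count trace of a CARS execution, the
#' per-band selection frequencies of a CARS result, the metric table of an
#' experiment, and the residual diagnostics of a prediction set.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @name tanninfuse-plots
NULL

#' @rdname tanninfuse-plots
#' @export
autoplot.sample_set <- function(object, ...) {
  spec_long <- function(block, sensor) {
    m <- spectra_matrix(block)
    tibble::tibble(sensor = sensor,
                   wavelength = spectra_wavelengths(block),
                   reflectance = colMeans(m))
  }
  df <- dplyr::bind_rows(spec_long(object$vnir, "VNIR"),
                         spec_long(object$swir, "SWIR"))
  ggplot(df, aes(x = .data$wavelength, y = .data$reflectance)) +
    geom_line() +
    facet_wrap(vars(.data$sensor), scales = "free_x") +
    labs(x = "wavelength (nm)", y = "mean reflectance") +
    theme_minimal()
}

#' @rdname tanninfuse-plots
#' @export
autoplot.cars_trace <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(c("n_retained", "rmsecv"),
                        names_to = "panel", values_to = "value")
  ggplot(df, aes(x = .data$iteration, y = .data$value)) +
    geom_line() +
    geom_point(data = dplyr::filter(df, .data$best), colour = "red") +
    facet_wrap(vars(.data$panel), ncol = 1, scales = "free_y") +
    labs(x = "Monte-Carlo iteration", y = NULL) +
    theme_minimal()
}

#' @rdname tanninfuse-plots
#' @export
autoplot.cars_result <- function(object, ...) {
  df <- tidy(object)
  x_var <- if (all(is.na(df$wavelength))) "band" else "wavelength"
  ggplot(df, aes(x = .data[[x_var]], y = .data$frequency,
                 fill = .data$selected)) +
    geom_col(width = if (x_var == "wavelength") diff(range(df[[x_var]])) / nrow(df) else 0.8) +
    geom_hline(yintercept = object$config$frequency_threshold, linetype = 2) +
    labs(x = if (x_var == "wavelength") "wavelength (nm)" else "band index",
         y = "selection frequency") +
    theme_minimal()
}

#' @rdname tanninfuse-plots
#' @export
autoplot.tannin_experiment <- function(object, ...) {
  ggplot(radar_data(object),
         aes(x = .data$variant, y = .data$value, fill = .data$family)) +
    geom_col(position = "dodge") +
    facet_grid(rows = vars(.data$metric), cols = vars(.data$set),
               scales = "free_y") +
    labs(x = NULL, y = NULL) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname tanninfuse-plots
#' @export
autoplot.residual_summary <- function(object, ...) {
  ggplot(object$residuals, aes(x = .data$residual)) +
    geom_histogram(bins = 20, colour = "white") +
    labs(x = "residual (predicted - reference, %)", y = "count") +
    theme_minimal()
}
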