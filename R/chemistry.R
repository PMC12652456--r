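#' Fit a tannic-acid standard curve
#'
#' Ordinary least-squares line relating absorbance at 525 nm to tannic-acid
#' concentration (mg/mL), inverted at prediction time: given a measured
#' absorbance, the curve returns the concentration `c` used by
#' [tannin_from_assay()].
#'
#' @param points Data frame with columns `concentration` (mg/mL) and
#'   `absorbance`, at least two distinct points.
#' @return A `standard_curve` (list with `slope`, `intercept` of the
#'   absorbance-on-concentration line, plus the fit).
#' @examples
#' fit_standard_curve(data.frame(concentration = 0:3, absorbance = c(0, 2, 4, 6)))
#' @export
fit_standard_curve <- function(points) {
  assert_that_(is.data.frame(points) &&
                 all(c("concentration", "absorbance") %in% names(points)),
               "`points` needs columns `concentration` and `absorbance`.")
  assert_that_(nrow(points) >= 2, "at least two standard points are required.")
  assert_that_(stats::var(points$concentration) > 0,
               "standard concentrations are degenerate (constant).")
  assert_that_(stats::var(points$absorbance) > 0,
               "standard absorbances are degenerate (constant).")
  fit <- stats::lm(absorbance ~ concentration, data = points)
  slope <- unname(coef(fit)[2])
  assert_that_(abs(slope) > .Machine$double.eps,
               "standard curve slope is zero; cannot invert.")
  structure(list(slope = slope, intercept = unname(coef(fit)[1]), fit = fit),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve: absorbance = %.4f + %.4f * c (mg/mL)>\n",
              x$intercept, x$slope))
  invisible(x)
}

#' Concentration from absorbance via a standard curve
#'
#' @param curve A [fit_standard_curve()] result.
#' @param absorbance Numeric absorbance value(s) at 525 nm.
#' @return Concentration(s) in mg/mL.
#' @export
concentration_from_absorbance <- function(curve, absorbance) {
  assert_that_(inherits(curve, "standard_curve"), "`curve` must be a standard_curve.")
  (absorbance - curve$intercept) / curve$slope
}

#' Average assay replicates
#'
#' Each sample's spectrophotometric assay is run three times and averaged;
#' this is the plain arithmetic mean (averaging happens on the absorbance
#' scale before curve inversion — with a linear curve the order is
#' immaterial).
#'
#' @param values Numeric vector of replicate measurements (>= 1).
#' @return The arithmetic mean.
#' @export
average_replicates <- function(values) {
  assert_that_(is.numeric(values) && length(values) >= 1,
               "`values` must be a non-empty numeric vector.")
  mean(values)
}

#' Tannin content from the spectrophotometric assay
#'
#' Converts an assay record to tannin content on a dry-matter basis:
#' `T = (2 * c / m) * 100 * 100 / (100 - H)`, where `c` is the tannic-acid
#' concentration (mg/mL) read off the standard curve from the (replicate-mean)
#' absorbance at 525 nm, `m` the sample mass (mg) and `H` the moisture
#' content (%). `2c/m` is the extracted mass fraction (the leading 2 folds in
#' the extraction volume and dilution of the standardized protocol), the
#' first 100 converts it to percent, and `100/(100 - H)` rescales to dry
#' matter (so `T` doubles between `H = 0` and `H = 50`).
#'
#' @param curve A [fit_standard_curve()] result.
#' @param absorbance Numeric absorbance replicate(s); averaged before
#'   inversion.
#' @param mass_mg Sample mass in mg (> 0).
#' @param moisture_pct Moisture content `H` in % (`0 <= H < 100`).
#' @return Tannin content `T` in %.
#' @examples
#' curve <- fit_standard_curve(data.frame(concentration = 0:1, absorbance = 0:1))
#' tannin_from_assay(curve, absorbance = 5, mass_mg = 1000, moisture_pct = 0) # 1
#' @export
tannin_from_assay <- function(curve, absorbance, mass_mg, moisture_pct = 0) {
  assert_that_(is.numeric(mass_mg) && mass_mg > 0, "`mass_mg` must be > 0.")
  assert_that_(is.numeric(moisture_pct) && moisture_pct >= 0 && moisture_pct < 100,
               "`moisture_pct` must be in [0, 100).")
  conc <- concentration_from_absorbance(curve, average_replicates(absorbance))
  (2 * conc / mass_mg) * 100 * 100 / (100 - moisture_pct)
}
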