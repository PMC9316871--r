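#' Fit a TROLOX calibration line
#'
#' Ordinary least-squares line through (concentration, signal) standards,
#' where the signal is the DPPH peak-area ratio of the reacted solution to
#' the radical blank. Because TROLOX consumes the radical, the slope is
#' expected to be negative and the intercept close to 1 (no scavenging at
#' zero concentration).
#'
#' @param standards Data frame with one row per calibration level and the
#'   columns named by `concentration` and `signal`.
#' @param concentration,signal Column names (strings) holding the TROLOX
#'   concentration in mM and the measured signal.
#' @return An object of class `calibration_curve` with fields `slope`
#'   (signal units per mM), `intercept`, `pearson_r`, `conc_range`
#'   (min/max mM of the standards) and `n_levels`.
#' @examples
#' std <- tibble::tibble(
#'   concentration = seq(0, 0.3, length.out = 7),
#'   signal = 1 - 3 * seq(0, 0.3, length.out = 7)
#' )
#' fit_calibration(std)
#' @export
fit_calibration <- function(standards, concentration = "concentration",
                            signal = "signal") {
  stopifnot(is.data.frame(standards))
  for (col in c(concentration, signal)) {
    if (!col %in% names(standards)) abort(sprintf("column '%s' not found.", col))
  }
  x <- standards[[concentration]]
  y <- standards[[signal]]
  if (length(x) < 3) abort("at least 3 calibration points are required.")
  if (anyNA(x) || anyNA(y)) abort("calibration points must not contain NA.")
  if (var(x) == 0) abort("calibration concentrations have zero variance.")
  fit <- lm(y ~ x)
  structure(
    list(
      slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      pearson_r = cor(x, y),
      conc_range = range(x),
      n_levels = length(unique(x))
    ),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("<calibration_curve>\n")
  cat(sprintf("  signal = %.4f x conc + %.4f   (r = %.4f)\n",
              x$slope, x$intercept, x$pearson_r))
  cat(sprintf("  range: %.3g to %.3g mM over %d levels\n",
              x$conc_range[1], x$conc_range[2], x$n_levels))
  invisible(x)
}

#' Peak-area signal ratio
#'
#' Radical-scavenging signal of a sample: the DPPH peak area after reaction
#' divided by the area of the unreacted radical blank. A ratio of 1 means no
#' scavenging; 0 means complete decolorization of the radical solution.
#'
#' @param blank_area Peak area of the radical blank (must be positive).
#' @param sample_area Peak area after reaction with the sample (non-negative).
#' @return Numeric vector of ratios in `[0, Inf)`.
#' @export
signal_ratio <- function(blank_area, sample_area) {
  if (any(!is.finite(blank_area)) || any(blank_area <= 0)) {
    abort("`blank_area` must be positive.")
  }
  if (any(sample_area < 0)) abort("`sample_area` must be non-negative.")
  sample_area / blank_area
}

#' Convert a signal ratio to a TEAC value
#'
#' Inverts the calibration line: `TEAC = (ratio - intercept) / slope`.
#' Negative raw values are clamped to 0 mM (a compound cannot have negative
#' antioxidant capacity) and flagged; values beyond the calibrated
#' concentration range are flagged as extrapolated.
#'
#' @param ratio Signal ratio(s), see [signal_ratio()].
#' @param curve A [fit_calibration()] result.
#' @return A tibble with columns `teac` (mM), `clamped` and `extrapolated`.
#' @export
teac_from_signal <- function(ratio, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope == 0) abort("calibration slope is zero; cannot invert.")
  raw <- (ratio - curve$intercept) / curve$slope
  tibble(
    teac = pmax(raw, 0),
    clamped = raw < 0,
    extrapolated = pmax(raw, 0) > curve$conc_range[2]
  )
}

#' Summarise replicate TEAC determinations
#'
#' Mean and relative standard deviation (RSD, percent, sample sd with n-1
#' denominator) of replicate measurements of one compound.
#'
#' @param teacs Numeric vector of replicate TEAC values (mM), length >= 2.
#' @return A tibble with columns `mean_teac` (mM), `rsd` (percent) and
#'   `n_replicates`.
#' @export
replicate_summary <- function(teacs) {
  if (length(teacs) < 2) abort("at least 2 replicates are required.")
  m <- mean(teacs)
  if (m == 0) abort("mean TEAC is zero; RSD is undefined.")
  tibble(mean_teac = m, rsd = 100 * sd(teacs) / m, n_replicates = length(teacs))
}

#' Recovery of a spiked standard
#'
#' Accuracy expressed as measured/nominal concentration in percent.
#'
#' @param measured Measured concentration(s), mM.
#' @param nominal Nominal (spiked) concentration(s), mM; must be positive.
#' @return Numeric vector of recoveries in percent.
#' @export
recovery <- function(measured, nominal) {
  if (any(nominal <= 0)) abort("`nominal` must be positive.")
  100 * measured / nominal
}

#' TEAC determination for a table of peak-area measurements
#'
#' Convenience wrapper for a whole injection table: computes the signal
#' ratio per injection, converts it to a TEAC value with the calibration
#' curve, and summarises replicates per compound.
#'
#' @param data Data frame with columns `compound_id`, `blank_area` and
#'   `sample_area` (one row per injection).
#' @param curve A [fit_calibration()] result.
#' @return A tibble with one row per compound: `compound_id`, `mean_teac`
#'   (mM), `rsd` (percent), `n_replicates`, and flags `any_clamped` /
#'   `any_extrapolated`.
#' @export
measure_teac <- function(data, curve) {
  stopifnot(is.data.frame(data))
  for (col in c("compound_id", "blank_area", "sample_area")) {
    if (!col %in% names(data)) abort(sprintf("column '%s' not found.", col))
  }
  per_injection <- dplyr::bind_cols(
    data["compound_id"],
    teac_from_signal(signal_ratio(data$blank_area, data$sample_area), curve)
  )
  per_injection |>
    dplyr::group_by(.data$compound_id) |>
    dplyr::summarise(
      mean_teac = mean(.data$teac),
      rsd = if (mean(.data$teac) > 0 && dplyr::n() > 1) {
        100 * sd(.data$teac) / mean(.data$teac)
      } else {
        NA_real_
      },
      n_replicates = dplyr::n(),
      any_clamped = any(.data$clamped),
      any_extrapolated = any(.data$extrapolated),
      .groups = "drop"
    )
}

#' Method-verification summary
#'
#' Assembles the verification statistics of the assay: recoveries of spiked
#' standards, the RSD of accuracy replicates, the RSD of precision
#' replicates, and whether the calibration met a linearity requirement.
#'
#' @param recoveries Numeric vector of recoveries (percent).
#' @param accuracy_teacs Replicate TEAC values (mM) from the accuracy study.
#' @param precision_teacs Replicate TEAC values (mM) from the precision study.
#' @param curve A [fit_calibration()] result.
#' @param min_abs_r Minimum absolute Pearson r of the calibration considered
#'   linear (default 0.999).
#' @return A one-row tibble: recovery range, accuracy/precision RSDs and the
#'   `linear_range_ok` flag.
#' @export
verification_report <- function(recoveries, accuracy_teacs, precision_teacs,
                                curve, min_abs_r = 0.999) {
  if (any(recoveries <= 0)) abort("recoveries must be positive.")
  tibble(
    recovery_min = min(recoveries),
    recovery_max = max(recoveries),
    rsd_accuracy = replicate_summary(accuracy_teacs)$rsd,
    rsd_precision = replicate_summary(precision_teacs)$rsd,
    linear_range_ok = abs(curve$pearson_r) >= min_abs_r
  )
}
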