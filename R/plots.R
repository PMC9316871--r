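#' Calibration-line plot
#'
#' Standards and the fitted TROLOX line, annotated with the equation.
#'
#' @param object A [fit_calibration()] result.
#' @param standards Optional tibble of the calibration points
#'   (`concentration`, `signal`) to overlay.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot calibration_curve
#' @export
autoplot.calibration_curve <- function(object, standards = NULL, ...) {
  p <- ggplot2::ggplot() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept) +
    ggplot2::labs(
      x = "TROLOX concentration (mM)", y = "Signal (peak-area ratio)",
      title = sprintf("signal = %.4f x conc + %.4f (r = %.4f)",
                      object$slope, object$intercept, object$pearson_r)
    ) +
    ggplot2::xlim(object$conc_range)
  if (!is.null(standards)) {
    p <- p + ggplot2::geom_point(
      data = standards,
      ggplot2::aes(x = .data$concentration, y = .data$signal))
  }
  p
}

#' Correlation-versus-size ladder plot
#'
#' Training (and, when available, external) correlation coefficient `r`
#' against the number of descriptors in the model: the training curve can
#' only rise with size, while the external curve peaking at an intermediate
#' size exposes overfitting beyond it.
#'
#' @param object A [build_model_ladder()] result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot model_ladder
#' @export
autoplot.model_ladder <- function(object, ...) {
  stats <- object$statistics
  long <- stats |>
    dplyr::select(dplyr::any_of(c("model_size", "r_tr", "r_ext"))) |>
    tidyr::pivot_longer(-"model_size", names_to = "set", values_to = "r") |>
    dplyr::mutate(set = dplyr::recode(.data$set,
                                      r_tr = "training", r_ext = "test"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$model_size, y = .data$r,
                                     linetype = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = stats$model_size) +
    ggplot2::labs(x = "Number of descriptors in the model",
                  y = "Correlation coefficient r")
}

#' @export
plot.model_ladder <- function(x, ...) print(autoplot(x, ...))

#' Observed-versus-predicted linearity plot
#'
#' @param model An [fit_mlr()] model.
#' @param newdata Optional test tibble plotted alongside the training set.
#' @return A ggplot object.
#' @export
plot_linearity <- function(model, newdata = NULL) {
  stopifnot(inherits(model, "mlr_model"))
  tab <- tibble(observed = model$train_y, predicted = model$fitted,
                set = "train")
  if (!is.null(newdata)) {
    tab <- dplyr::bind_rows(tab, tibble(
      observed = newdata[[model$activity]],
      predicted = predict(model, newdata),
      set = "test"
    ))
  }
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$observed, y = .data$predicted,
                                    colour = .data$set)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Observed TEAC (mM)", y = "Predicted TEAC (mM)")
}
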