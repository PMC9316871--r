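#' Leverage (hat) values of training and query compounds
#'
#' `h = x (X'X)^-1 x'` per row, with the intercept column appended to the
#' design. Training rows are queried against their own design; query rows
#' use the training design's cross-product, so a compound far outside the
#' training descriptor space gets a large leverage.
#'
#' @param x_train Numeric matrix of training descriptor values (full rank
#'   together with the intercept).
#' @param x_query Optional matrix of query rows with the same columns;
#'   `NULL` returns the training leverages.
#' @return Numeric vector of leverages, one per (query) row.
#' @export
leverages <- function(x_train, x_query = NULL) {
  x_train <- as.matrix(x_train)
  z_train <- cbind(1, x_train)
  xtx_inv <- tryCatch(chol2inv(chol(crossprod(z_train))),
                      error = function(e) abort("training design is rank deficient."))
  z <- if (is.null(x_query)) z_train else cbind(1, as.matrix(x_query))
  rowSums((z %*% xtx_inv) * z)
}

#' Warning leverage of a Williams plot
#'
#' The conventional applicability-domain cutoff `h* = 3 (p + 1) / n` for a
#' model with `p` descriptors fitted on `n` training compounds; compounds
#' with leverage above `h*` are structurally influential (X-outliers).
#'
#' @param n_train Number of training compounds.
#' @param p Number of descriptors.
#' @return The warning leverage.
#' @export
warning_leverage <- function(n_train, p) {
  n_train <- check_count(n_train, "n_train")
  p <- check_count(p, "p")
  if (n_train <= p + 1) abort("`n_train` must exceed `p` + 1.")
  3 * (p + 1) / n_train
}

#' Williams-plot applicability-domain report
#'
#' Pairs every compound's leverage with its standardized residual: training
#' rows use the leave-one-out residual divided by the cross-validated RMSE
#' (the plot is of cross-validated residuals), test rows use the external
#' residual divided by the external RMSE. A compound is an X-outlier when
#' its leverage exceeds the warning leverage `h* = 3(p+1)/n`, and a
#' Y-outlier (response outlier) when its standardized residual exceeds 3 in
#' absolute value. No compound is dropped: the report has one row per
#' training and test compound.
#'
#' @param model An [fit_mlr()] model.
#' @param newdata Optional external test tibble with the model descriptors
#'   and activity column.
#' @return A tibble of class `ad_report` with columns `compound_id`, `set`,
#'   `leverage`, `std_residual`, `x_outlier`, `y_outlier`, and attributes
#'   `h_star`, `rmse_cv` and (with a test set) `rmse_ext`.
#' @export
williams_report <- function(model, newdata = NULL) {
  stopifnot(inherits(model, "mlr_model"))
  internal <- loo_cv(model)
  loo <- attr(internal, "loo_predictions")
  h_star <- warning_leverage(model$n_train, model$p)
  train_tab <- tibble(
    compound_id = loo$compound_id,
    set = "train",
    leverage = loo$leverage,
    std_residual = (loo$observed - loo$loo_predicted) / internal$rmse_cv
  )
  out <- train_tab
  rmse_ext <- NULL
  if (!is.null(newdata)) {
    ext <- external_validation(model, newdata)
    pred <- predict(model, newdata)
    y_ext <- newdata[[model$activity]]
    rmse_ext <- ext$rmse_ext
    test_tab <- tibble(
      compound_id = if ("compound_id" %in% names(newdata)) newdata$compound_id
                    else sprintf("ext_%03d", seq_len(nrow(newdata))),
      set = "test",
      leverage = leverages(model$train_x,
                           as.matrix(newdata[model$descriptor_names])),
      std_residual = (y_ext - pred) / rmse_ext
    )
    out <- dplyr::bind_rows(train_tab, test_tab)
  }
  out$x_outlier <- out$leverage > h_star
  out$y_outlier <- abs(out$std_residual) > 3
  attr(out, "h_star") <- h_star
  attr(out, "rmse_cv") <- internal$rmse_cv
  attr(out, "rmse_ext") <- rmse_ext
  class(out) <- c("ad_report", class(out))
  out
}

#' Williams plot
#'
#' Standardized cross-validated residuals against leverage, with the
#' warning-leverage and the +/- 3 standardized-residual guide lines;
#' the canonical applicability-domain diagnostic.
#'
#' @param object An [williams_report()] result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot ad_report
#' @export
autoplot.ad_report <- function(object, ...) {
  h_star <- attr(object, "h_star")
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$leverage, y = .data$std_residual,
                               colour = .data$set)) +
    ggplot2::geom_hline(yintercept = c(-3, 3), linetype = "dashed") +
    ggplot2::geom_vline(xintercept = h_star, linetype = "dotted") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Leverage (hat value)",
      y = "Standardized cross-validated residual",
      title = "Williams plot",
      subtitle = sprintf("h* = %.3f; |residual| > 3 marks response outliers", h_star)
    )
}

#' @export
plot.ad_report <- function(x, ...) print(autoplot(x, ...))
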