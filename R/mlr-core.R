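#' Fit an ordinary least-squares multi-descriptor regression
#'
#' Fits `activity ~ descriptors` by OLS (QR decomposition, via [stats::lm()])
#' with an intercept always included, and reports coefficient standard
#' errors from the unbiased residual variance. The fitted training data are
#' kept inside the object so the cross-validation and applicability-domain
#' tools can re-derive anything they need.
#'
#' @param data Training tibble containing the activity column and the
#'   descriptor columns.
#' @param descriptors Character vector of descriptor column names to use;
#'   `NULL` uses every numeric column except the identifier and activity.
#' @param activity Name of the activity column (default `"teac"`).
#' @return An object of class `mlr_model`.
#' @export
fit_mlr <- function(data, descriptors = NULL, activity = "teac") {
  stopifnot(is.data.frame(data))
  if (!activity %in% names(data)) abort(sprintf("column '%s' not found.", activity))
  if (is.null(descriptors)) descriptors <- descriptor_columns(data, activity)
  missing <- setdiff(descriptors, names(data))
  if (length(missing) > 0) {
    abort(paste0("descriptor column(s) not found: ", paste(missing, collapse = ", ")))
  }
  x <- as.matrix(data[descriptors])
  y <- data[[activity]]
  n <- nrow(x)
  p <- ncol(x)
  if (n <= p + 1) abort("need more compounds than descriptors plus intercept.")
  fit <- lm(y ~ x)
  cf <- coef(fit)
  if (anyNA(cf)) abort("design is rank deficient (collinear descriptors).")
  sm <- summary(fit)
  se <- sm$coefficients[, "Std. Error"]
  structure(
    list(
      descriptor_names = descriptors,
      coefficients = setNames(unname(cf[-1]), descriptors),
      coefficient_ses = setNames(unname(se[-1]), descriptors),
      intercept = unname(cf[1]),
      intercept_se = unname(se[1]),
      n_train = n,
      p = p,
      sigma = sm$sigma,
      fitted = unname(fit$fitted.values),
      residuals = unname(fit$residuals),
      train_x = x,
      train_y = y,
      compound_id = if ("compound_id" %in% names(data)) data$compound_id else
        sprintf("row_%03d", seq_len(n)),
      activity = activity
    ),
    class = "mlr_model"
  )
}

#' @export
print.mlr_model <- function(x, digits = 4, ...) {
  cat("<mlr_model>\n")
  terms <- paste(sprintf("%+.*f(±%.*f) x %s", digits, x$coefficients,
                         digits, x$coefficient_ses, x$descriptor_names),
                 collapse = " ")
  cat(sprintf("  %s = %s %+.*f(±%.*f)\n", x$activity, terms,
              digits, x$intercept, digits, x$intercept_se))
  cat(sprintf("  n = %d, p = %d, s = %.4g\n", x$n_train, x$p, x$sigma))
  invisible(x)
}

#' @export
predict.mlr_model <- function(object, newdata, ...) {
  stopifnot(is.data.frame(newdata) || is.matrix(newdata))
  missing <- setdiff(object$descriptor_names, colnames(newdata))
  if (length(missing) > 0) {
    abort(paste0("descriptor column(s) missing from newdata: ",
                 paste(missing, collapse = ", ")))
  }
  x <- as.matrix(as.data.frame(newdata)[object$descriptor_names])
  drop(object$intercept + x %*% object$coefficients)
}

#' Adjusted coefficient of determination
#'
#' `1 - (1 - R2) * (n - 1) / (n - p - 1)` for a model with `p` descriptors
#' and an intercept fitted on `n` observations.
#'
#' @param r2 Coefficient of determination.
#' @param n Number of training observations.
#' @param p Number of descriptors (excluding the intercept).
#' @return The adjusted R-squared.
#' @export
adjusted_r2 <- function(r2, n, p) {
  n <- check_count(n, "n"); p <- check_count(p, "p")
  if (n <= p + 1) abort("`n` must exceed `p` + 1.")
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' F-ratio of a regression from its R-squared
#'
#' `F = (R2 / p) / ((1 - R2) / (n - p - 1))`, with the p-value from the F
#' distribution on `(p, n - p - 1)` degrees of freedom.
#'
#' @inheritParams adjusted_r2
#' @return A one-row tibble with `f` and `p_value`.
#' @export
fisher_f <- function(r2, n, p) {
  n <- check_count(n, "n"); p <- check_count(p, "p")
  if (n <= p + 1) abort("`n` must exceed `p` + 1.")
  if (r2 < 0 || r2 >= 1) abort("`r2` must be in [0, 1); an exact fit has infinite F.")
  f <- (r2 / p) / ((1 - r2) / (n - p - 1))
  tibble(f = f, p_value = pf(f, p, n - p - 1, lower.tail = FALSE))
}

#' Lin's concordance correlation coefficient
#'
#' Agreement between observed and predicted values, penalizing both
#' dispersion and location differences:
#' `2 * S_xy / (S_xx + S_yy + n * (mean_x - mean_y)^2)` with sums of
#' centred squares/products.
#'
#' @param observed,predicted Numeric vectors of equal length (>= 2).
#' @return The concordance correlation in `[-1, 1]`.
#' @export
concordance_cc <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2) {
    abort("`observed` and `predicted` must have equal length >= 2.")
  }
  xc <- observed - mean(observed)
  yc <- predicted - mean(predicted)
  denom <- sum(xc^2) + sum(yc^2) +
    length(observed) * (mean(observed) - mean(predicted))^2
  if (denom == 0) abort("both vectors are constant; concordance undefined.")
  2 * sum(xc * yc) / denom
}

#' Training-set fitting statistics
#'
#' The fitting-criteria block for a fitted model: R-squared and its adjusted
#' form, the standard error of estimate `s = sqrt(RSS / (n - p - 1))`, the
#' F-ratio with p-value, training RMSE `sqrt(RSS / n)` and MAE, and the
#' concordance correlation between observed and fitted activities.
#'
#' @param model An [fit_mlr()] model.
#' @return A one-row tibble of class `fit_statistics`.
#' @export
fit_statistics <- function(model) {
  stopifnot(inherits(model, "mlr_model"))
  y <- model$train_y
  res <- model$residuals
  n <- model$n_train
  p <- model$p
  tss <- sum((y - mean(y))^2)
  if (tss == 0) abort("activity has zero variance.")
  rss <- sum(res^2)
  r2 <- 1 - rss / tss
  ftab <- if (r2 < 1) fisher_f(r2, n, p) else tibble(f = Inf, p_value = 0)
  out <- tibble(
    r2 = r2,
    r2_adj = adjusted_r2(r2, n, p),
    s = sqrt(rss / (n - p - 1)),
    f = ftab$f,
    p_value = ftab$p_value,
    rmse_tr = sqrt(rss / n),
    mae_tr = mean(abs(res)),
    ccc_tr = concordance_cc(y, model$fitted)
  )
  class(out) <- c("fit_statistics", class(out))
  out
}

#' @method glance mlr_model
#' @export
glance.mlr_model <- function(x, ...) {
  out <- fit_statistics(x)
  class(out) <- class(out)[-1]
  out$n_train <- x$n_train
  out$p <- x$p
  out
}

#' @method tidy mlr_model
#' @export
tidy.mlr_model <- function(x, ...) {
  est <- c(x$intercept, x$coefficients)
  se <- c(x$intercept_se, x$coefficient_ses)
  stat <- est / se
  tibble(
    term = c("(Intercept)", x$descriptor_names),
    estimate = unname(est),
    std.error = unname(se),
    statistic = unname(stat),
    p.value = 2 * stats::pt(abs(stat), df = x$n_train - x$p - 1,
                            lower.tail = FALSE)
  )
}
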