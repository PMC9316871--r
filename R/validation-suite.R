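# Hat diagonal of the intercept-augmented training design.
hat_diagonal <- function(x) {
  z <- cbind(1, x)
  xtx_inv <- tryCatch(chol2inv(chol(crossprod(z))),
                      error = function(e) abort("design is rank deficient."))
  rowSums((z %*% xtx_inv) * z)
}

#' Leave-one-out cross-validation of an MLR model
#'
#' Computes the predictive residual sum of squares `PRESS = sum((y_i -
#' yhat_(-i))^2)` via the hat-diagonal identity `e_i / (1 - h_ii)` (which is
#' algebraically exact for OLS, not an approximation), and from it
#' `Q2_LOO = 1 - PRESS/TSS`, the cross-validated RMSE `sqrt(PRESS/n)` and
#' MAE, and the concordance correlation between observed activities and
#' their leave-one-out predictions.
#'
#' @param model An [fit_mlr()] model.
#' @return A one-row tibble of class `internal_validation` with columns
#'   `q2_loo`, `rmse_cv`, `mae_cv`, `press_cv`, `ccc_cv`, and an attribute
#'   `loo_predictions` holding the per-compound held-out predictions.
#' @export
loo_cv <- function(model) {
  stopifnot(inherits(model, "mlr_model"))
  if (model$n_train <= model$p + 2) abort("too few compounds for LOO.")
  h <- hat_diagonal(model$train_x)
  if (any(h >= 1 - 1e-12)) {
    abort("a compound has leverage 1; its held-out prediction is undefined.")
  }
  loo_res <- model$residuals / (1 - h)
  y <- model$train_y
  tss <- sum((y - mean(y))^2)
  press <- sum(loo_res^2)
  loo_pred <- y - loo_res
  out <- tibble(
    q2_loo = 1 - press / tss,
    rmse_cv = sqrt(press / model$n_train),
    mae_cv = mean(abs(loo_res)),
    press_cv = press,
    ccc_cv = concordance_cc(y, loo_pred)
  )
  attr(out, "loo_predictions") <- tibble(
    compound_id = model$compound_id,
    observed = y,
    loo_predicted = loo_pred,
    leverage = h
  )
  class(out) <- c("internal_validation", class(out))
  out
}

#' Leave-many-out cross-validation
#'
#' Repeatedly removes a random fraction of the training compounds, refits
#' the model on the retained rows and predicts the held-out ones. The
#' summary `Q2_LMO` pools the held-out squared errors over all iterations,
#' each against the retained-subset mean as baseline:
#' `1 - sum(errors^2) / sum((y_out - mean(y_retained))^2)`. Pooling (rather
#' than averaging per-iteration ratios) keeps the statistic stable for
#' small held-out groups and makes it converge to `Q2_LOO` as the fraction
#' shrinks towards one compound; the per-iteration ratios are still
#' reported for inspection.
#'
#' @param model An [fit_mlr()] model.
#' @param leave_fraction Fraction of compounds held out per iteration, in
#'   `(0, 0.5]`. Default 0.3.
#' @param n_iter Number of random iterations. Default 100.
#' @param seed Integer seed; results are reproducible under it.
#' @return A one-row tibble with `q2_lmo` (pooled over iterations),
#'   `leave_fraction` and `n_iter`; per-iteration Q2 ratios are in the
#'   `per_iteration` attribute.
#' @export
lmo_cv <- function(model, leave_fraction = 0.3, n_iter = 100, seed = 1L) {
  stopifnot(inherits(model, "mlr_model"))
  check_number(leave_fraction, "leave_fraction", min = 0, strict = TRUE)
  if (leave_fraction > 0.5) abort("`leave_fraction` must be at most 0.5.")
  n_iter <- check_count(n_iter, "n_iter")
  n <- model$n_train
  n_out <- max(1L, ceiling(leave_fraction * n))
  if (n - n_out < model$p + 2) abort("retained set too small to refit.")
  z <- cbind(1, model$train_x)
  y <- model$train_y
  iters <- with_seed(seed, purrr::map(seq_len(n_iter), function(i) {
    out_idx <- sample.int(n, n_out)
    fit <- lm.fit(z[-out_idx, , drop = FALSE], y[-out_idx])
    pred <- drop(z[out_idx, , drop = FALSE] %*% fit$coefficients)
    c(press = sum((y[out_idx] - pred)^2),
      baseline = sum((y[out_idx] - mean(y[-out_idx]))^2))
  }))
  press <- vapply(iters, `[[`, numeric(1), "press")
  baseline <- vapply(iters, `[[`, numeric(1), "baseline")
  if (sum(baseline) == 0) abort("held-out activities have zero spread in every iteration.")
  out <- tibble(q2_lmo = 1 - sum(press) / sum(baseline),
                leave_fraction = leave_fraction, n_iter = n_iter)
  attr(out, "per_iteration") <- ifelse(baseline > 0, 1 - press / baseline,
                                       NA_real_)
  out
}

#' External (test-set) validation
#'
#' Predictive performance on compounds never used in fitting: the external
#' PRESS, RMSE and MAE; the squared Pearson correlation of observed vs
#' predicted (`r2_ext`); the three external predictive determination
#' coefficients, which differ only in their reference variance
#' (`q2_f1`: external deviations from the *training* mean; `q2_f2`: from
#' the external mean; `q2_f3`: external mean squared error against the
#' training variance per observation); and the external concordance
#' correlation.
#'
#' @param model An [fit_mlr()] model.
#' @param newdata Test tibble with the model's descriptors and the activity
#'   column, at least 3 rows.
#' @param activity Name of the activity column (default: the one the model
#'   was fitted with).
#' @return A one-row tibble of class `external_validation`.
#' @export
external_validation <- function(model, newdata, activity = NULL) {
  stopifnot(inherits(model, "mlr_model"))
  activity <- activity %||% model$activity
  if (!activity %in% names(newdata)) abort(sprintf("column '%s' not found.", activity))
  if (nrow(newdata) < 3) abort("at least 3 external compounds are required.")
  y_ext <- newdata[[activity]]
  pred <- predict(model, newdata)
  n_ext <- length(y_ext)
  err <- y_ext - pred
  press <- sum(err^2)
  train_mean <- mean(model$train_y)
  train_tss_per_n <- sum((model$train_y - train_mean)^2) / model$n_train
  ext_tss <- sum((y_ext - mean(y_ext))^2)
  if (ext_tss == 0) abort("external activities have zero variance; Q2_F2 undefined.")
  out <- tibble(
    rmse_ext = sqrt(press / n_ext),
    mae_ext = mean(abs(err)),
    press_ext = press,
    r2_ext = cor(y_ext, pred)^2,
    q2_f1 = 1 - press / sum((y_ext - train_mean)^2),
    q2_f2 = 1 - press / ext_tss,
    q2_f3 = 1 - (press / n_ext) / train_tss_per_n,
    ccc_ext = concordance_cc(y_ext, pred)
  )
  class(out) <- c("external_validation", class(out))
  out
}

#' Y-scrambling (response permutation) test
#'
#' Refits the model after randomly permuting the activities, leaving the
#' descriptors untouched, and records the scrambled R2 and Q2_LOO for each
#' permutation. A real structure-activity relationship should have both
#' scrambled means far below the unscrambled statistics, with mean scrambled
#' R2 above mean scrambled Q2.
#'
#' @param model An [fit_mlr()] model.
#' @param n_permutations Number of permutations, at least 10. Default 100.
#' @param seed Integer seed (Fisher-Yates permutations are drawn from it).
#' @return An object of class `y_scramble_result`: a list with
#'   `per_permutation` (tibble of scrambled `r2` and `q2_loo`),
#'   `mean_r2`, `mean_q2`, `n_permutations` and `seed`.
#' @export
y_scramble <- function(model, n_permutations = 100, seed = 1L) {
  stopifnot(inherits(model, "mlr_model"))
  n_permutations <- check_count(n_permutations, "n_permutations", min = 10L)
  y <- model$train_y
  if (var(y) == 0) abort("activity has zero variance; scrambling is meaningless.")
  z <- cbind(1, model$train_x)
  h <- hat_diagonal(model$train_x)
  per <- with_seed(seed, purrr::map_dfr(seq_len(n_permutations), function(i) {
    py <- sample(y)
    fit <- lm.fit(z, py)
    res <- fit$residuals
    tss <- sum((py - mean(py))^2)
    tibble(
      permutation = i,
      r2 = 1 - sum(res^2) / tss,
      q2_loo = 1 - sum((res / (1 - h))^2) / tss
    )
  }))
  structure(
    list(
      per_permutation = per,
      mean_r2 = mean(per$r2),
      mean_q2 = mean(per$q2_loo),
      n_permutations = n_permutations,
      seed = seed
    ),
    class = "y_scramble_result"
  )
}

#' @export
print.y_scramble_result <- function(x, ...) {
  cat("<y_scramble_result>\n")
  cat(sprintf("  %d permutations: mean scrambled R2 = %.3f, mean scrambled Q2 = %.3f\n",
              x$n_permutations, x$mean_r2, x$mean_q2))
  invisible(x)
}

#' Model-acceptability rule set
#'
#' Applies the literal acceptance thresholds for a TEAC regression model:
#' training R2 at least 0.6, external R2 at least 0.6, external concordance
#' correlation at least 0.85, training RMSE smaller than the cross-validated
#' RMSE, and a Y-scrambling test in which the mean scrambled R2 exceeds the
#' mean scrambled Q2 while both stay below the real model's R2 and Q2_LOO.
#'
#' @param fit A [fit_statistics()] row.
#' @param internal A [loo_cv()] row.
#' @param external An [external_validation()] row.
#' @param yscr Optionally, a [y_scramble()] result; `NULL` leaves the
#'   scrambling flag `NA`.
#' @return A one-row tibble of logical flags: `r2_ok`, `r2_ext_ok`,
#'   `ccc_ok`, `rmse_order_ok`, `yscr_ok`, and `all_ok` (conjunction of the
#'   non-missing flags).
#' @export
acceptability_check <- function(fit, internal, external, yscr = NULL) {
  flags <- tibble(
    r2_ok = fit$r2 >= 0.6,
    r2_ext_ok = external$r2_ext >= 0.6,
    ccc_ok = external$ccc_ext >= 0.85,
    rmse_order_ok = fit$rmse_tr < internal$rmse_cv,
    yscr_ok = if (is.null(yscr)) NA else {
      yscr$mean_r2 > yscr$mean_q2 &&
        yscr$mean_r2 < fit$r2 && yscr$mean_q2 < internal$q2_loo
    }
  )
  flags$all_ok <- all(unlist(flags), na.rm = TRUE)
  flags
}

#' Full validation report for one model
#'
#' Runs the fitting statistics, leave-one-out validation, the multivariate
#' correlation (K) indices of the model's descriptor block, and, when a test
#' set is supplied, the external validation, then returns everything as one
#' row whose column names follow the conventional QSAR report labels
#' (`R2`, `R2_adj`, `s`, `F`, `Kxx`, `DK`, `RMSE_tr`, `MAE_tr`, `CCC_tr`,
#' `Q2_LOO`, `RMSE_cv`, `MAE_cv`, `PRESS_cv`, `CCC_cv`, `RMSE_ext`,
#' `MAE_ext`, `PRESS_ext`, `R2_ext`, `Q2_F1`, `Q2_F2`, `Q2_F3`, `CCC_ext`).
#'
#' @param model An [fit_mlr()] model.
#' @param newdata Optional external test tibble.
#' @return A one-row tibble.
#' @export
validation_report <- function(model, newdata = NULL) {
  fit <- fit_statistics(model)
  internal <- loo_cv(model)
  k <- quik_filter(model$train_x, model$train_y)
  out <- tibble(
    N_tr = model$n_train,
    R2 = fit$r2, R2_adj = fit$r2_adj, s = fit$s, F = fit$f, p = fit$p_value,
    Kxx = k$kxx, DK = k$delta_k,
    RMSE_tr = fit$rmse_tr, MAE_tr = fit$mae_tr, CCC_tr = fit$ccc_tr,
    Q2_LOO = internal$q2_loo, RMSE_cv = internal$rmse_cv,
    MAE_cv = internal$mae_cv, PRESS_cv = internal$press_cv,
    CCC_cv = internal$ccc_cv
  )
  if (!is.null(newdata)) {
    ext <- external_validation(model, newdata)
    out <- dplyr::bind_cols(out, tibble(
      N_ex = nrow(newdata),
      RMSE_ext = ext$rmse_ext, MAE_ext = ext$mae_ext,
      PRESS_ext = ext$press_ext, R2_ext = ext$r2_ext,
      Q2_F1 = ext$q2_f1, Q2_F2 = ext$q2_f2, Q2_F3 = ext$q2_f3,
      CCC_ext = ext$ccc_ext
    ))
  }
  out
}

#' Write a validation report as JSON
#'
#' @param report A [validation_report()] row.
#' @param path Output file path.
#' @return `report`, invisibly.
#' @export
write_validation_json <- function(report, path) {
  jsonlite::write_json(as.list(report), path, auto_unbox = TRUE, digits = NA)
  invisible(report)
}
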