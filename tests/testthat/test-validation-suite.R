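test_that("the LOO fast path equals the explicit refit oracle", {
  tab <- random_problem(30, 3, noise_sd = 0.2, seed = 20)
  m <- fit_mlr(tab)
  internal <- loo_cv(m)
  loo <- attr(internal, "loo_predictions")
  brute <- brute_loo_predictions(as.matrix(tab[m$descriptor_names]), tab$teac)
  expect_equal(loo$loo_predicted, brute, tolerance = 1e-10)
  press_brute <- sum((tab$teac - brute)^2)
  expect_equal(internal$press_cv, press_brute, tolerance = 1e-10)
  expect_equal(internal$rmse_cv, sqrt(press_brute / 30), tolerance = 1e-12)
})

test_that("PRESS dominates RSS and Q2 stays below R2 on noisy data", {
  for (seed in 21:23) {
    tab <- random_problem(40, 4, noise_sd = 0.5, seed = seed)
    m <- fit_mlr(tab)
    internal <- loo_cv(m)
    rss <- sum(m$residuals^2)
    expect_gte(internal$press_cv, rss)
    expect_lt(internal$q2_loo, fit_statistics(m)$r2)
  }

  exact <- tibble::tibble(x1 = rnorm(20), x2 = rnorm(20))
  exact$teac <- exact$x1 - exact$x2 + 0.3
  m0 <- fit_mlr(exact)
  internal0 <- loo_cv(m0)
  expect_equal(internal0$q2_loo, 1, tolerance = 1e-8)
  expect_lt(internal0$press_cv, 1e-16)
})

test_that("leave-many-out is seeded, exact on noiseless data, and near LOO for tiny groups", {
  exact <- tibble::tibble(x1 = rnorm(30), x2 = rnorm(30))
  exact$teac <- 0.5 * exact$x1 + exact$x2
  m0 <- fit_mlr(exact)
  expect_equal(lmo_cv(m0, 0.2, 20, seed = 1)$q2_lmo, 1, tolerance = 1e-8)

  tab <- random_problem(60, 3, noise_sd = 0.3, seed = 24)
  m <- fit_mlr(tab)
  a <- lmo_cv(m, 0.3, 50, seed = 7)
  b <- lmo_cv(m, 0.3, 50, seed = 7)
  expect_identical(attr(a, "per_iteration"), attr(b, "per_iteration"))
  expect_false(identical(attr(a, "per_iteration"),
                         attr(lmo_cv(m, 0.3, 50, seed = 8), "per_iteration")))

  near_loo <- lmo_cv(m, 1 / 60, 200, seed = 9)
  expect_lt(abs(near_loo$q2_lmo - loo_cv(m)$q2_loo), 0.05)
})

test_that("external validation metrics match a term-by-term oracle", {
  tab <- random_problem(40, 3, noise_sd = 0.3, seed = 25)
  train <- tab[1:30, ]
  test <- tab[31:40, ]
  m <- fit_mlr(train)
  ext <- external_validation(m, test)

  pred <- predict(m, test)
  y <- test$teac
  n_ext <- 10
  press <- sum((y - pred)^2)
  train_mean <- mean(train$teac)
  expect_equal(ext$press_ext, press, tolerance = 1e-12)
  expect_equal(ext$rmse_ext, sqrt(press / n_ext), tolerance = 1e-12)
  expect_equal(ext$rmse_ext^2 * n_ext, ext$press_ext, tolerance = 1e-12)
  expect_equal(ext$mae_ext, mean(abs(y - pred)), tolerance = 1e-12)
  expect_equal(ext$q2_f1, 1 - press / sum((y - train_mean)^2), tolerance = 1e-12)
  expect_equal(ext$q2_f2, 1 - press / sum((y - mean(y))^2), tolerance = 1e-12)
  expect_equal(ext$q2_f3,
               1 - (press / n_ext) /
                 (sum((train$teac - train_mean)^2) / nrow(train)),
               tolerance = 1e-12)
  expect_equal(ext$r2_ext, cor(y, pred)^2, tolerance = 1e-12)
  expect_equal(ext$ccc_ext, lin_ccc_oracle(y, pred), tolerance = 1e-12)

  # perfect predictions drive every metric to its ideal
  exact <- tibble::tibble(x1 = rnorm(30), x2 = rnorm(30))
  exact$teac <- exact$x1 + 2 * exact$x2
  m0 <- fit_mlr(exact)
  probe <- tibble::tibble(x1 = rnorm(5), x2 = rnorm(5))
  probe$teac <- probe$x1 + 2 * probe$x2
  perfect <- external_validation(m0, probe)
  expect_equal(perfect$rmse_ext, 0, tolerance = 1e-8)
  expect_equal(perfect$q2_f1, 1, tolerance = 1e-8)
  expect_equal(perfect$q2_f2, 1, tolerance = 1e-8)
  expect_equal(perfect$ccc_ext, 1, tolerance = 1e-8)
})

test_that("Y-scrambling is seeded, ordered, and centred near p/(n-1) on pure noise", {
  set.seed(26)
  tab <- tibble::as_tibble(as.data.frame(matrix(rnorm(40 * 3), 40, 3)))
  names(tab) <- c("x1", "x2", "x3")
  tab$teac <- rnorm(40)
  m <- fit_mlr(tab)

  scr <- y_scramble(m, 50, seed = 10)
  expect_identical(scr$per_permutation,
                   y_scramble(m, 50, seed = 10)$per_permutation)
  expect_true(all(scr$per_permutation$r2 >= scr$per_permutation$q2_loo))
  expect_gte(scr$mean_r2, scr$mean_q2)

  null_scr <- y_scramble(m, 500, seed = 11)
  # E[R2] = p/(n-1) for random regressors; allow Monte-Carlo slack
  expect_lt(abs(null_scr$mean_r2 - 3 / 39), 0.02)
})

test_that("acceptability flags apply the literal thresholds", {
  good <- acceptability_check(
    fit = tibble::tibble(r2 = 0.643, rmse_tr = 0.041),
    internal = tibble::tibble(rmse_cv = 0.047, q2_loo = 0.539),
    external = tibble::tibble(r2_ext = 0.859, ccc_ext = 0.913)
  )
  expect_true(good$r2_ok)
  expect_true(good$r2_ext_ok)
  expect_true(good$ccc_ok)
  expect_true(good$rmse_order_ok)
  expect_true(is.na(good$yscr_ok))

  weak <- acceptability_check(
    fit = tibble::tibble(r2 = 0.316, rmse_tr = 0.056),
    internal = tibble::tibble(rmse_cv = 0.060, q2_loo = 0.227),
    external = tibble::tibble(r2_ext = 0.657, ccc_ext = 0.703)
  )
  expect_false(weak$r2_ok)
  expect_false(weak$ccc_ok)

  exact <- tibble::tibble(x1 = rnorm(30), x2 = rnorm(30))
  exact$teac <- exact$x1 + exact$x2 + rnorm(30, 0, 0.05)
  m <- fit_mlr(exact)
  flags <- acceptability_check(fit_statistics(m), loo_cv(m),
                               external_validation(m, exact),
                               y_scramble(m, 20, seed = 1))
  expect_true(flags$r2_ok)
  expect_true(flags$yscr_ok)
})

test_that("the assembled validation report carries the conventional labels", {
  tab <- random_problem(40, 3, noise_sd = 0.3, seed = 27)
  m <- fit_mlr(tab[1:30, ])
  rep <- validation_report(m, tab[31:40, ])
  expect_true(all(c("R2", "R2_adj", "s", "F", "Kxx", "DK", "RMSE_tr", "MAE_tr",
                    "CCC_tr", "Q2_LOO", "RMSE_cv", "MAE_cv", "PRESS_cv",
                    "CCC_cv", "RMSE_ext", "MAE_ext", "PRESS_ext", "R2_ext",
                    "Q2_F1", "Q2_F2", "Q2_F3", "CCC_ext") %in% names(rep)))
  path <- withr::local_tempfile(fileext = ".json")
  write_validation_json(rep, path)
  back <- jsonlite::fromJSON(path)
  expect_equal(back$R2, rep$R2, tolerance = 1e-12)
})
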