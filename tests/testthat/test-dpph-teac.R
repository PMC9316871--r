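trolox_curve <- function() {
  conc <- seq(0, 0.3, length.out = 7)
  fit_calibration(tibble::tibble(concentration = conc,
                                 signal = -3.0101 * conc + 0.9997))
}

test_that("calibration recovers an exact line and matches the OLS oracle", {
  curve <- trolox_curve()
  expect_equal(curve$slope, -3.0101, tolerance = 1e-10)
  expect_equal(curve$intercept, 0.9997, tolerance = 1e-10)
  expect_equal(abs(curve$pearson_r), 1, tolerance = 1e-10)
  expect_equal(curve$conc_range, c(0, 0.3))
  expect_equal(curve$n_levels, 7)

  ident <- fit_calibration(tibble::tibble(concentration = c(0, 1, 2),
                                          signal = c(0, 1, 2)))
  expect_equal(ident$slope, 1)
  expect_equal(ident$intercept, 0, tolerance = 1e-12)

  set.seed(9)
  x <- runif(50, 0, 0.3)
  y <- 1 - 3 * x + rnorm(50, 0, 0.02)
  noisy <- fit_calibration(tibble::tibble(concentration = x, signal = y))
  # closed-form normal equations
  slope_hat <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(noisy$slope, slope_hat, tolerance = 1e-12)
  expect_equal(noisy$intercept, mean(y) - slope_hat * mean(x), tolerance = 1e-12)

  expect_error(fit_calibration(tibble::tibble(concentration = c(0, 1),
                                              signal = c(1, 0))), "3")
  expect_error(fit_calibration(tibble::tibble(concentration = c(1, 1, 1),
                                              signal = c(1, 2, 3))), "variance")
})

test_that("signal ratio is the sample/blank area quotient", {
  expect_equal(signal_ratio(1000, 1000), 1.0)
  expect_equal(signal_ratio(1000, 0), 0.0)
  expect_equal(signal_ratio(800, 200), 0.25)
  expect_error(signal_ratio(0, 10), "positive")
  expect_error(signal_ratio(100, -1), "non-negative")
})

test_that("TEAC inversion is the identity on the calibrated range and clamps below", {
  curve <- trolox_curve()
  expect_equal(teac_from_signal(0.9997, curve)$teac, 0, tolerance = 1e-12)

  grid <- seq(0, 0.3, length.out = 21)
  forward <- curve$slope * grid + curve$intercept
  round_trip <- teac_from_signal(forward, curve)
  expect_equal(round_trip$teac, grid, tolerance = 1e-12)
  expect_false(any(round_trip$clamped))
  expect_false(any(round_trip$extrapolated))

  clamped <- teac_from_signal(1.05, curve)
  expect_equal(clamped$teac, 0)
  expect_true(clamped$clamped)

  beyond <- teac_from_signal(curve$slope * 0.35 + curve$intercept, curve)
  expect_true(beyond$extrapolated)
  expect_equal(beyond$teac, 0.35, tolerance = 1e-12)

  flat <- curve
  flat$slope <- 0
  expect_error(teac_from_signal(0.5, flat), "slope")
})

test_that("replicate summaries and recoveries follow the analytical formulas", {
  same <- replicate_summary(c(0.1, 0.1, 0.1))
  expect_equal(same$mean_teac, 0.1)
  expect_equal(same$rsd, 0)

  trio <- replicate_summary(c(0.14, 0.15, 0.16))
  expect_equal(trio$mean_teac, 0.15)
  expect_equal(trio$rsd, 100 * 0.01 / 0.15, tolerance = 1e-12)

  expect_error(replicate_summary(c(0, 0)), "undefined")
  expect_error(replicate_summary(0.1), "2")

  expect_equal(recovery(0.15, 0.15), 100)
  expect_equal(recovery(0.1562, 0.15), 104.1333, tolerance = 1e-4)
  expect_equal(recovery(0, 0.15), 0)
  expect_error(recovery(0.1, 0), "positive")
})

test_that("a measurement table flows through to per-compound TEAC summaries", {
  curve <- trolox_curve()
  teac_true <- c(drug_a = 0.12, drug_b = 0.25)
  injections <- tidyr::expand_grid(compound_id = names(teac_true),
                                   replicate = 1:3) |>
    dplyr::mutate(
      blank_area = 1000,
      sample_area = 1000 * (curve$slope * teac_true[compound_id] +
                              curve$intercept)
    )
  out <- measure_teac(injections, curve)
  expect_equal(nrow(out), 2)
  expect_equal(out$mean_teac, unname(teac_true[out$compound_id]),
               tolerance = 1e-10)
  expect_equal(out$rsd, c(0, 0), tolerance = 1e-8)

  report <- verification_report(
    recoveries = c(96.9, 104.1),
    accuracy_teacs = c(0.14, 0.15, 0.16),
    precision_teacs = c(0.15, 0.15, 0.16),
    curve = curve
  )
  expect_true(report$linear_range_ok)
  expect_equal(report$recovery_max, 104.1)
})
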