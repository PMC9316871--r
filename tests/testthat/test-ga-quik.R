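test_that("the K index hits its closed-form anchors and the eigenvalue oracle", {
  set.seed(30)
  expect_equal(k_index(matrix(rnorm(20), 20, 1)), 0)

  x <- rnorm(25)
  expect_equal(k_index(cbind(x, 2 * x + 1)), 1, tolerance = 1e-12)

  block <- matrix(rnorm(40 * 5), 40, 5)
  block[, 2] <- 0.6 * block[, 1] + 0.4 * block[, 2]
  expect_equal(k_index(block), k_index_oracle(block), tolerance = 1e-12)
  expect_gte(k_index(block), 0)
  expect_lte(k_index(block), 1)

  # invariant to column order and sign flips
  expect_equal(k_index(block[, 5:1]), k_index(block), tolerance = 1e-12)
  flipped <- block
  flipped[, 3] <- -flipped[, 3]
  expect_equal(k_index(flipped), k_index(block), tolerance = 1e-12)

  expect_error(k_index(cbind(x, rep(1, 25))), "constant")
})

test_that("the QUIK filter reduces to |r| for one descriptor and rejects redundancy", {
  set.seed(31)
  x <- matrix(rnorm(30), 30, 1)
  y <- 0.7 * x[, 1] + rnorm(30, 0, 0.5)
  q <- quik_filter(x, y)
  expect_equal(q$kxx, 0)
  expect_equal(q$delta_k, abs(cor(x[, 1], y)), tolerance = 1e-12)

  # a response that duplicates a member of an already-collinear subset
  # brings no new information: Kxy stays at Kxx
  base <- rnorm(30)
  xx <- cbind(base, 0.98 * base + 0.02 * rnorm(30))
  dup <- quik_filter(xx, xx[, 1])
  expect_lt(dup$delta_k, 0.05)
  expect_false(dup$pass)

  # orthogonal response can even lower the index; never an error
  y_orth <- rnorm(30)
  q2 <- quik_filter(xx, y_orth)
  expect_equal(q2$kxy, k_index_oracle(cbind(xx, y_orth)), tolerance = 1e-12)
})

test_that("over-correlated descriptor pairs are flagged at the limit", {
  set.seed(32)
  a <- rnorm(60)
  b <- 0.76 * a + sqrt(1 - 0.76^2) * rnorm(60)
  c <- rnorm(60)
  x <- cbind(a = a, b = b, c = c)
  screen <- cross_correlation_screen(x, r_limit = 0.7)
  if (abs(cor(a, b)) > 0.7) {
    expect_true(screen$flagged)
    expect_true(all(sort(unlist(screen$pairs[1, 1:2])) == c("a", "b")))
  }
  expect_false(cross_correlation_screen(cbind(a = a, c = c), 0.7)$flagged)
  expect_false(cross_correlation_screen(x, 1.0)$flagged)
  dup <- cbind(a = a, b = a)
  expect_error(cross_correlation_screen(matrix(a, ncol = 1)), "two")
})

test_that("the GA equals exhaustive search on small instances", {
  set.seed(33)
  tab <- tibble::as_tibble(as.data.frame(matrix(rnorm(40 * 12), 40, 12)))
  names(tab) <- sprintf("v%02d", 1:12)
  tab$teac <- 0.8 * tab$v03 - 0.6 * tab$v07 + 0.5 * tab$v11 + rnorm(40, 0, 0.4)

  cfg <- ga_config(population_size = 60, generations = 80, seed = 5)
  res <- ga_select(tab, 3, cfg)

  # brute-force oracle: every 3-subset, Q2_LOO fitness, same pass rules
  desc <- sprintf("v%02d", 1:12)
  x <- as.matrix(tab[desc])
  y <- tab$teac
  best_fit <- -Inf; best_set <- NULL
  for (cols in asplit(combn(12, 3), 2)) {
    xs <- x[, cols, drop = FALSE]
    cm <- cor(xs)
    if (max(abs(cm[upper.tri(cm)])) > cfg$r_limit) next
    q <- quik_filter(xs, y, cfg$quik_delta)
    if (!q$pass) next
    pred <- brute_loo_predictions(xs, y)
    fit <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
    if (fit > best_fit) { best_fit <- fit; best_set <- desc[cols] }
  }
  expect_setequal(res$candidates$descriptors[[1]], best_set)
  expect_equal(res$candidates$fitness[1], best_fit, tolerance = 1e-10)
})

test_that("a single-descriptor GA recovers the dominant correlate", {
  set.seed(34)
  tab <- tibble::as_tibble(as.data.frame(matrix(rnorm(50 * 8), 50, 8)))
  names(tab) <- sprintf("v%d", 1:8)
  tab$teac <- tab$v5 + rnorm(50, 0, 0.2)
  res <- ga_select(tab, 1, ga_config(population_size = 20, generations = 30,
                                     seed = 6))
  exhaustive <- sapply(sprintf("v%d", 1:8), function(v) {
    pred <- brute_loo_predictions(as.matrix(tab[v]), tab$teac)
    1 - sum((tab$teac - pred)^2) / sum((tab$teac - mean(tab$teac))^2)
  })
  expect_equal(res$candidates$descriptors[[1]], names(which.max(exhaustive)))
})

test_that("the GA is deterministic under its seed and elitist across generations", {
  tab <- random_problem(40, 10, noise_sd = 0.4, seed = 35)
  cfg <- ga_config(population_size = 30, generations = 40, seed = 7)
  a <- ga_select(tab, 2, cfg)
  b <- ga_select(tab, 2, cfg)
  expect_identical(a$candidates, b$candidates)
  finite <- is.finite(a$history)
  expect_true(all(diff(a$history[finite]) >= -1e-12))
})

test_that("the model ladder saturates once the truth is reachable", {
  set.seed(36)
  tab <- tibble::as_tibble(as.data.frame(matrix(rnorm(40 * 6), 40, 6)))
  names(tab) <- sprintf("w%d", 1:6)
  tab$teac <- tab$w2 - 0.5 * tab$w4
  ladder <- build_model_ladder(tab, sizes = 1:3,
                               config = ga_config(population_size = 30,
                                                  generations = 40, seed = 8))
  stats <- ladder$statistics
  expect_equal(stats$model_size, 1:3)
  expect_equal(stats$R2[2], 1, tolerance = 1e-10)
  expect_equal(stats$R2[3], 1, tolerance = 1e-10)
  expect_true(all(diff(stats$R2) >= -1e-6))
  expect_true(all(c("R2", "Q2_LOO", "Kxx", "DK", "r_tr") %in% names(stats)))
})
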