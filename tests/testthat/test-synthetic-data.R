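test_that("generator honours dimensions, constant columns and the seed", {
  spec <- synthetic_spec(72, 300, block_size = 5, block_correlation = 0.8,
                         n_constant_columns = 3, seed = 1)
  tab <- generate_descriptors(spec)
  expect_equal(dim(tab), c(72, 301))          # + compound_id
  desc <- setdiff(names(tab), "compound_id")
  n_const <- sum(vapply(tab[desc], function(v) var(v) == 0, logical(1)))
  expect_equal(n_const, 3)
  expect_false(anyDuplicated(desc) > 0)

  expect_identical(tab, generate_descriptors(spec))
  spec2 <- synthetic_spec(72, 300, block_size = 5, block_correlation = 0.8,
                          n_constant_columns = 3, seed = 2)
  expect_false(identical(tab, generate_descriptors(spec2)))

  expect_error(synthetic_spec(2, 300, block_correlation = 1), "0, 1")
  expect_error(synthetic_spec(0, 10), "n_compounds")
})

test_that("within-block correlation matches the target at large n", {
  spec <- synthetic_spec(2000, 10, block_size = 5, block_correlation = 0.8,
                         seed = 42)
  tab <- generate_descriptors(spec)
  for (block in list(sprintf("D%03d", 1:5), sprintf("D%03d", 6:10))) {
    cm <- cor(as.matrix(tab[block]))
    offdiag <- cm[upper.tri(cm)]
    expect_true(all(offdiag > 0.75 & offdiag < 0.85))
  }
})

test_that("noiseless activity is the exact linear truth and refits exactly", {
  coefs <- c(alpha = 1.5, beta = -0.7)
  spec <- synthetic_spec(30, 6, true_coefficients = coefs,
                         true_intercept = 0.25, noise_sd = 0, seed = 3)
  ds <- generate_activity(generate_descriptors(spec), spec)

  z <- function(v) (v - min(v)) / diff(range(v))
  expect_equal(ds$table$teac,
               0.25 + 1.5 * z(ds$table$alpha) - 0.7 * z(ds$table$beta),
               tolerance = 1e-12)

  norm <- normalize_descriptors(ds$table)
  m <- fit_mlr(norm, names(coefs))
  expect_equal(unname(m$coefficients[names(coefs)]), unname(coefs),
               tolerance = 1e-10)
  expect_equal(m$intercept, 0.25, tolerance = 1e-10)

  spec_one <- synthetic_spec(15, 3, true_coefficients = c(a = 1),
                             true_intercept = 0, noise_sd = 0, seed = 4)
  ds1 <- generate_activity(generate_descriptors(spec_one), spec_one)
  expect_equal(ds1$table$teac, z(ds1$table$a), tolerance = 1e-12)
})

test_that("clipping at zero floors the activity", {
  spec <- synthetic_spec(25, 4, true_coefficients = c(a = 0.1),
                         true_intercept = -10, noise_sd = 0.01,
                         clip_at_zero = TRUE, seed = 5)
  ds <- generate_activity(generate_descriptors(spec), spec)
  expect_true(all(ds$table$teac == 0))
})

test_that("missing informative column is an error", {
  spec <- synthetic_spec(20, 3, true_coefficients = c(zz = 1), seed = 6)
  tab <- generate_descriptors(spec)
  tab$zz <- NULL
  expect_error(generate_activity(tab, spec), "zz")
})

test_that("study-scale dataset has the contracted shape and activity scale", {
  ds <- make_study_dataset(7)
  expect_equal(nrow(ds$table), 72)
  expect_gte(ncol(ds$table) - 2, 200)
  expect_true(all(c("Mor16e", "RDF145p", "C-018", "CATS2D_06_AL") %in%
                    names(ds$table)))
  expect_identical(ds$table, make_study_dataset(7)$table)

  means <- vapply(1:10, function(s) {
    tab <- make_study_dataset(s)$table
    expect_true(all(tab$teac >= 0 & tab$teac <= 0.45))
    mean(tab$teac)
  }, numeric(1))
  expect_true(all(means >= 0 & means <= 0.2))
})

test_that("descriptor tables round-trip through CSV with the id first and activity last", {
  ds <- generate_activity(
    generate_descriptors(synthetic_spec(10, 4, true_coefficients = c(a = 1),
                                        seed = 8)),
    synthetic_spec(10, 4, true_coefficients = c(a = 1), seed = 8)
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_descriptor_table(ds$table, path)
  back <- read_descriptor_table(path)
  header <- names(back)
  expect_equal(header[1], "compound_id")
  expect_equal(header[length(header)], "teac")
  expect_equal(as.data.frame(back[sort(names(back))]),
               as.data.frame(ds$table[sort(names(ds$table))]),
               tolerance = 1e-12)
})
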