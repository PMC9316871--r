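#' Specify a synthetic descriptor/activity dataset
#'
#' Defines the statistical structure of a simulated compound-by-descriptor
#' table: how many compounds and candidate descriptors to draw, which
#' descriptors carry a real linear signal (and with what coefficients, on the
#' min-max-normalized scale), the residual noise level of the activity, the
#' within-block correlation of redundant descriptor families, and how many
#' degenerate constant columns to plant. The generator emulates the shape of
#' a software-computed molecular-descriptor matrix at desk scale: descriptor
#' values are latent standard normals (blocks share a common factor so that
#' each within-block pair has the requested correlation in expectation), and
#' the activity is a linear function of the *normalized* informative columns
#' plus Gaussian noise, optionally clipped at zero because a TEAC is
#' physically non-negative.
#'
#' @param n_compounds Number of rows (compounds).
#' @param n_descriptors Total number of descriptor columns, including the
#'   informative and constant ones.
#' @param true_coefficients Named numeric vector: activity units (mM TEAC) per
#'   unit of min-max-normalized descriptor. The names become the informative
#'   descriptor columns. May be empty for a pure-noise table.
#' @param true_intercept Activity intercept in mM.
#' @param noise_sd Residual standard deviation of the activity, in mM.
#' @param block_size Number of descriptors per correlated block among the
#'   non-informative columns. `1` disables block structure.
#' @param block_correlation Target pairwise Pearson correlation within a
#'   block, in `[0, 1)`.
#' @param n_constant_columns Number of zero-variance columns to plant.
#' @param clip_at_zero If `TRUE`, negative activities are set to 0 (clipped
#'   points are kept, not resampled).
#' @param seed Integer seed; the same spec and seed reproduce the dataset
#'   bit for bit.
#'
#' @return An object of class `synthetic_spec`.
#' @seealso [generate_descriptors()], [generate_activity()],
#'   [make_study_dataset()]
#' @export
synthetic_spec <- function(n_compounds,
                           n_descriptors,
                           true_coefficients = numeric(),
                           true_intercept = 0,
                           noise_sd = 0,
                           block_size = 1L,
                           block_correlation = 0,
                           n_constant_columns = 0L,
                           clip_at_zero = FALSE,
                           seed = 1L) {
  n_compounds <- check_count(n_compounds, "n_compounds", min = 2L)
  n_descriptors <- check_count(n_descriptors, "n_descriptors", min = 1L)
  block_size <- check_count(block_size, "block_size", min = 1L)
  n_constant_columns <- check_count(n_constant_columns, "n_constant_columns", min = 0L)
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(block_correlation, "block_correlation")
  if (block_correlation < 0 || block_correlation >= 1) {
    abort("`block_correlation` must be in [0, 1).")
  }
  if (length(true_coefficients) > 0 &&
      (is.null(names(true_coefficients)) || any(names(true_coefficients) == ""))) {
    abort("`true_coefficients` must be a fully named numeric vector.")
  }
  if (anyDuplicated(names(true_coefficients))) {
    abort("informative descriptor names must be unique.")
  }
  n_informative <- length(true_coefficients)
  if (n_descriptors < n_informative + n_constant_columns) {
    abort("`n_descriptors` must cover the informative and constant columns.")
  }
  structure(
    list(
      n_compounds = n_compounds,
      n_descriptors = n_descriptors,
      informative_names = names(true_coefficients),
      true_coefficients = true_coefficients,
      true_intercept = true_intercept,
      noise_sd = noise_sd,
      block_size = block_size,
      block_correlation = block_correlation,
      n_constant_columns = n_constant_columns,
      clip_at_zero = clip_at_zero,
      seed = check_count(seed, "seed", min = -.Machine$integer.max)
    ),
    class = "synthetic_spec"
  )
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("<synthetic_spec>\n")
  cat(sprintf("  %d compounds x %d descriptors (%d informative, %d constant)\n",
              x$n_compounds, x$n_descriptors,
              length(x$informative_names), x$n_constant_columns))
  cat(sprintf("  noise sd %.4g mM, block rho %.2f (size %d), clip at zero: %s, seed %d\n",
              x$noise_sd, x$block_correlation, x$block_size,
              x$clip_at_zero, x$seed))
  invisible(x)
}

#' Draw a synthetic descriptor table
#'
#' Generates the compound-by-descriptor matrix described by a
#' [synthetic_spec()]. Informative descriptors are drawn independently;
#' the remaining stochastic columns are organised in blocks sharing a latent
#' factor, `x = sqrt(rho) * f + sqrt(1 - rho) * eps`, so each within-block
#' pair has correlation `rho` in expectation. Constant columns are planted at
#' a fixed value. Column order is shuffled (deterministically under the
#' spec's seed) so downstream selection cannot rely on position.
#'
#' @param spec A [synthetic_spec()].
#' @return A tibble with a `compound_id` column followed by
#'   `spec$n_descriptors` named descriptor columns.
#' @export
generate_descriptors <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_compounds
  m <- spec$n_descriptors
  n_inf <- length(spec$informative_names)
  n_noise <- m - n_inf - spec$n_constant_columns
  rho <- spec$block_correlation

  with_seed(spec$seed, {
    cols <- list()
    for (nm in spec$informative_names) cols[[nm]] <- rnorm(n)
    if (n_noise > 0) {
      n_blocks <- ceiling(n_noise / spec$block_size)
      idx <- 1L
      for (b in seq_len(n_blocks)) {
        size_b <- min(spec$block_size, n_noise - (b - 1L) * spec$block_size)
        f <- rnorm(n)
        for (j in seq_len(size_b)) {
          x <- if (rho > 0 && size_b > 1) {
            sqrt(rho) * f + sqrt(1 - rho) * rnorm(n)
          } else {
            rnorm(n)
          }
          cols[[sprintf("D%03d", idx)]] <- x
          idx <- idx + 1L
        }
      }
    }
    for (k in seq_len(spec$n_constant_columns)) {
      cols[[sprintf("const%02d", k)]] <- rep(0.5, n)
    }
    ord <- sample.int(length(cols))
    cols <- cols[ord]
    tibble::as_tibble(c(
      list(compound_id = sprintf("cmpd_%03d", seq_len(n))),
      cols
    ))
  })
}

#' Append a simulated activity to a descriptor table
#'
#' Computes `activity = intercept + sum(coef * normalized descriptor) + noise`
#' where each informative column is min-max normalized over the rows of
#' `data`, then (optionally) clips negative values at zero. The noise stream
#' is seeded independently of the descriptor draw so the two stages are
#' individually reproducible.
#'
#' @param data Descriptor tibble from [generate_descriptors()].
#' @param spec The same [synthetic_spec()] used to generate `data`.
#' @return An object of class `synthetic_dataset`: a list with `table` (the
#'   input tibble plus a `teac` activity column, in mM) and `truth` (the
#'   informative names, coefficients, intercept and noise sd actually used).
#' @export
generate_activity <- function(data, spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  missing <- setdiff(spec$informative_names, names(data))
  if (length(missing) > 0) {
    abort(paste0("informative descriptor(s) not in table: ",
                 paste(missing, collapse = ", ")))
  }
  n <- nrow(data)
  signal <- rep(spec$true_intercept, n)
  for (nm in spec$informative_names) {
    x <- data[[nm]]
    rng <- range(x)
    if (diff(rng) == 0) abort(sprintf("informative column '%s' is constant.", nm))
    z <- (x - rng[1]) / diff(rng)
    signal <- signal + spec$true_coefficients[[nm]] * z
  }
  y <- with_seed(spec$seed + 1L, signal + rnorm(n, 0, spec$noise_sd))
  if (spec$clip_at_zero) y <- pmax(y, 0)
  out <- data
  out$teac <- y
  structure(
    list(
      table = out,
      truth = list(
        informative_names = spec$informative_names,
        true_coefficients = spec$true_coefficients,
        true_intercept = spec$true_intercept,
        noise_sd = spec$noise_sd
      )
    ),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset>\n")
  cat(sprintf("  %d compounds x %d descriptors + activity\n",
              nrow(x$table), ncol(x$table) - 2L))
  cat(sprintf("  informative: %s\n",
              paste(x$truth$informative_names, collapse = ", ")))
  invisible(x)
}

#' Study-scale synthetic dataset
#'
#' One-call generator for a dataset with the shape the modelling workflow
#' assumes: 72 compounds, 208 candidate descriptors of which four carry the
#' signal, redundant descriptor families (blocks of five at within-block
#' correlation 0.8), four constant columns, and activities clipped at zero.
#' The four informative descriptors reuse the names and coefficients of the
#' fixed four-variable TEAC equation (see [published_model()]), with residual
#' noise sd 0.0428 mM, so the planted truth matches the scale of the real
#' screening data (TEAC roughly 0 to 0.3 mM).
#'
#' @param seed Integer seed.
#' @return A `synthetic_dataset` (see [generate_activity()]).
#' @export
make_study_dataset <- function(seed = 1L) {
  m4 <- published_model(4)
  coefs <- setNames(m4$terms$coefficient, m4$terms$descriptor)
  spec <- synthetic_spec(
    n_compounds = 72,
    n_descriptors = 208,
    true_coefficients = coefs,
    true_intercept = m4$intercept,
    noise_sd = 0.0428,
    block_size = 5,
    block_correlation = 0.8,
    n_constant_columns = 4,
    clip_at_zero = TRUE,
    seed = seed
  )
  generate_activity(generate_descriptors(spec), spec)
}

#' Read or write a descriptor table as delimited text
#'
#' The on-disk layout is a CSV whose header row carries the descriptor names,
#' with the compound identifier first and the activity column (`teac`, mM)
#' last when present.
#'
#' @param data A descriptor tibble.
#' @param path File path.
#' @return `read_descriptor_table()` returns a tibble;
#'   `write_descriptor_table()` returns `data` invisibly.
#' @export
write_descriptor_table <- function(data, path) {
  stopifnot(is.data.frame(data))
  front <- intersect("compound_id", names(data))
  back <- intersect("teac", names(data))
  rest <- setdiff(names(data), c(front, back))
  readr::write_csv(data[c(front, rest, back)], path)
  invisible(data)
}

#' @rdname write_descriptor_table
#' @export
read_descriptor_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

# Numeric descriptor columns of a table (everything except identifiers and
# the activity).
descriptor_columns <- function(data, activity = "teac") {
  cand <- setdiff(names(data), c("compound_id", activity, ".set"))
  cand[vapply(data[cand], is.numeric, logical(1))]
}
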