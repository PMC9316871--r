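#' Multivariate correlation (K) index of a variable block
#'
#' Eigenvalue-dispersion measure of how collinear a set of columns is: with
#' `lambda` the eigenvalues of the block's correlation matrix and
#' `lambda' = lambda / sum(lambda)`,
#' `K = sum(|lambda'_j - 1/p|) / (2 * (p - 1) / p)`.
#' K is 0 for mutually orthogonal columns, 1 for perfectly collinear ones,
#' and 0 by convention for a single column (a lone variable carries no
#' redundancy). It is invariant to column order and to sign flips.
#'
#' @param block Numeric matrix or data frame with at least one column and no
#'   constant column.
#' @return The K index in `[0, 1]`.
#' @export
k_index <- function(block) {
  x <- as.matrix(block)
  if (!is.numeric(x) || ncol(x) < 1) abort("`block` must be a numeric matrix.")
  if (any(apply(x, 2, var) == 0)) {
    abort("`block` contains a constant column; correlation is undefined.")
  }
  if (ncol(x) == 1) return(0)
  k_from_correlation(cor(x))
}

# K index straight from a correlation matrix (used on precomputed slices
# inside the GA loop).
k_from_correlation <- function(cmat) {
  p <- ncol(cmat)
  if (p == 1) return(0)
  lam <- eigen(cmat, symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, 0)
  lam <- lam / sum(lam)
  sum(abs(lam - 1 / p)) / (2 * (p - 1) / p)
}

#' QUIK-rule filter for a candidate descriptor subset
#'
#' Compares the multivariate correlation of the descriptor block alone
#' (`Kxx`) with that of the block augmented by the response (`Kxy`). A
#' subset passes when adding the response increases the index by at least
#' `delta_threshold` (`delta_k = Kxy - Kxx >= threshold`): the response must
#' bring correlation the descriptors do not already share among themselves.
#'
#' @param x Numeric matrix or data frame of the candidate descriptors.
#' @param y Response vector.
#' @param delta_threshold Minimum `delta_k` to pass. Default 0.05.
#' @return A list with `kxx`, `kxy`, `delta_k` and the logical `pass`.
#' @export
quik_filter <- function(x, y, delta_threshold = 0.05) {
  x <- as.matrix(x)
  if (length(y) != nrow(x)) abort("`y` must match the rows of `x`.")
  kxx <- k_index(x)
  kxy <- k_index(cbind(x, y))
  list(kxx = kxx, kxy = kxy, delta_k = kxy - kxx,
       pass = (kxy - kxx) >= delta_threshold)
}

#' Flag over-correlated descriptor pairs in a model
#'
#' Scans the pairwise Pearson correlations of a fitted model's descriptors
#' and lists every pair whose absolute correlation exceeds `r_limit`; such
#' pairs carry the same information twice and make one of the two
#' descriptors redundant.
#'
#' @param model An [fit_mlr()] model with at least two descriptors, or a
#'   numeric matrix of descriptor columns.
#' @param r_limit Absolute-correlation limit. Default 0.7.
#' @return A list with `flagged` (logical) and `pairs` (tibble of
#'   descriptor pairs and their correlation, empty when none offend).
#' @export
cross_correlation_screen <- function(model, r_limit = 0.7) {
  x <- if (inherits(model, "mlr_model")) model$train_x else as.matrix(model)
  if (ncol(x) < 2) abort("at least two descriptors are required.")
  cmat <- cor(x)
  nm <- colnames(cmat) %||% sprintf("x%d", seq_len(ncol(cmat)))
  pairs <- which(upper.tri(cmat) & abs(cmat) > r_limit, arr.ind = TRUE)
  tab <- tibble(
    descriptor_1 = nm[pairs[, 1]],
    descriptor_2 = nm[pairs[, 2]],
    r = cmat[pairs]
  )
  list(flagged = nrow(tab) > 0, pairs = tab)
}

#' Configuration of the genetic-algorithm descriptor search
#'
#' The evolutionary search starts from a population of random fixed-size
#' descriptor subsets and evolves them with tournament selection (k = 2),
#' uniform crossover repaired to the exact subset size, a per-offspring
#' mutation that swaps one member for a random outsider, and elitism. The
#' defaults (population 200, 2000 generations, 20% mutation) are the
#' configuration of the original TEAC study; tests and examples use smaller
#' budgets.
#'
#' @param population_size Number of candidate subsets per generation.
#' @param generations Number of evolutionary rounds.
#' @param mutation_probability Per-offspring probability of a one-member
#'   swap, in `[0, 1]`.
#' @param fitness Fitness metric: `"q2_loo"` (default) or `"r2"`.
#' @param elitism Number of top candidates copied unchanged.
#' @param quik_delta QUIK `delta_k` threshold; failing subsets get fitness
#'   `-Inf`. Default 0.05.
#' @param r_limit Cross-correlation limit within a subset; offending
#'   subsets get fitness `-Inf`. Default 0.7.
#' @param seed Integer seed making the whole search reproducible.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(population_size = 200, generations = 2000,
                      mutation_probability = 0.20,
                      fitness = c("q2_loo", "r2"),
                      elitism = 2, quik_delta = 0.05, r_limit = 0.7,
                      seed = 1L) {
  fitness <- match.arg(fitness)
  check_number(mutation_probability, "mutation_probability", min = 0)
  if (mutation_probability > 1) abort("`mutation_probability` must be <= 1.")
  structure(
    list(
      population_size = check_count(population_size, "population_size", min = 2L),
      generations = check_count(generations, "generations"),
      mutation_probability = mutation_probability,
      fitness = fitness,
      elitism = check_count(elitism, "elitism", min = 0L),
      quik_delta = quik_delta,
      r_limit = r_limit,
      seed = check_count(seed, "seed", min = -.Machine$integer.max)
    ),
    class = "ga_config"
  )
}

# Subset fitness evaluator with caching. Correlation slices come from the
# precomputed full correlation matrix, so each evaluation only does a small
# eigen-decomposition and a p-column least-squares solve.
make_subset_evaluator <- function(x, y, config) {
  n <- nrow(x)
  tss <- sum((y - mean(y))^2)
  cor_x <- suppressWarnings(cor(x))
  cor_xy <- drop(suppressWarnings(cor(x, y)))
  cache <- new.env(hash = TRUE, parent = emptyenv())
  function(subset) {
    key <- paste(subset, collapse = ".")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    p <- length(subset)
    val <- local({
      cs <- cor_x[subset, subset, drop = FALSE]
      if (p >= 2 && max(abs(cs[upper.tri(cs)])) > config$r_limit) return(-Inf)
      kxx <- k_from_correlation(cs)
      cxy <- rbind(cbind(cs, cor_xy[subset]), c(cor_xy[subset], 1))
      if ((k_from_correlation(cxy) - kxx) < config$quik_delta) return(-Inf)
      z <- cbind(1, x[, subset, drop = FALSE])
      xtx <- crossprod(z)
      ch <- tryCatch(chol(xtx), error = function(e) NULL)
      if (is.null(ch)) return(-Inf)
      inv <- chol2inv(ch)
      beta <- inv %*% crossprod(z, y)
      res <- y - drop(z %*% beta)
      if (config$fitness == "r2") {
        1 - sum(res^2) / tss
      } else {
        h <- rowSums((z %*% inv) * z)
        if (any(h >= 1 - 1e-12)) return(-Inf)
        1 - sum((res / (1 - h))^2) / tss
      }
    })
    cache[[key]] <- val
    val
  }
}

# One uniform-crossover child of two sorted subsets, repaired to size p:
# shared members are always kept, the remainder drawn from the symmetric
# difference.
crossover_subsets <- function(a, b, p) {
  shared <- intersect(a, b)
  pool <- setdiff(union(a, b), shared)
  need <- p - length(shared)
  if (need > 0) {
    extra <- if (length(pool) == 1) pool else sample(pool, need)
    sort(c(shared, extra))
  } else {
    sort(shared)
  }
}

#' Genetic-algorithm descriptor-subset selection
#'
#' Evolves fixed-size descriptor subsets to maximise a cross-validated
#' fitness, discarding candidates that fail the QUIK rule or contain
#' over-correlated descriptor pairs (their fitness is `-Inf`). The search is
#' deterministic under the configuration seed; elite candidates are carried
#' over unchanged, so the best fitness never decreases across generations.
#'
#' @param data Tibble of (typically filtered and normalized) descriptors
#'   plus the activity column.
#' @param model_size Number of descriptors per candidate subset.
#' @param config A [ga_config()].
#' @param activity Name of the activity column (default `"teac"`).
#' @return An object of class `ga_result`: a list with `candidates` (tibble
#'   of deduplicated surviving subsets ranked by fitness, with their QUIK
#'   indices), `best_model` (the top subset refitted with [fit_mlr()]),
#'   `model_size`, `config`, and `history` (best population fitness after
#'   each generation; non-decreasing whenever `elitism > 0`).
#' @export
ga_select <- function(data, model_size, config = ga_config(), activity = "teac") {
  stopifnot(is.data.frame(data), inherits(config, "ga_config"))
  desc <- descriptor_columns(data, activity)
  p <- check_count(model_size, "model_size")
  m <- length(desc)
  if (m < p) abort("fewer descriptors than `model_size`.")
  n <- nrow(data)
  if (p >= n / 3) abort("`model_size` must be below a third of the compounds.")
  x <- as.matrix(data[desc])
  y <- data[[activity]]
  evaluate <- make_subset_evaluator(x, y, config)

  pop_size <- config$population_size
  history <- numeric(config$generations)
  with_seed(config$seed, {
    population <- replicate(pop_size, sort(sample.int(m, p)), simplify = FALSE)
    fitness <- vapply(population, evaluate, numeric(1))
    for (gen in seq_len(config$generations)) {
      ord <- order(fitness, decreasing = TRUE)
      n_elite <- min(config$elitism, pop_size)
      offspring <- population[ord[seq_len(n_elite)]]
      while (length(offspring) < pop_size) {
        pick <- function() {
          duel <- sample.int(pop_size, 2)
          duel[which.max(fitness[duel])]
        }
        child <- crossover_subsets(population[[pick()]], population[[pick()]], p)
        if (runif(1) < config$mutation_probability) {
          out_pos <- sample.int(p, 1)
          outsiders <- setdiff(seq_len(m), child)
          if (length(outsiders) > 0) {
            repl <- if (length(outsiders) == 1) outsiders else sample(outsiders, 1)
            child <- sort(c(child[-out_pos], repl))
          }
        }
        offspring[[length(offspring) + 1L]] <- child
      }
      population <- offspring
      fitness <- vapply(population, evaluate, numeric(1))
      history[gen] <- max(fitness)
    }
  })

  keys <- vapply(population, paste, character(1), collapse = ".")
  keep <- !duplicated(keys) & is.finite(fitness)
  if (!any(keep)) abort("no candidate subset survived the QUIK and correlation filters.")
  survivors <- population[keep]
  surv_fit <- fitness[keep]
  ord <- order(surv_fit, decreasing = TRUE)
  survivors <- survivors[ord]
  surv_fit <- surv_fit[ord]

  k_stats <- purrr::map(survivors, function(s) {
    quik_filter(x[, s, drop = FALSE], y, config$quik_delta)
  })
  candidates <- tibble(
    rank = seq_along(survivors),
    descriptors = purrr::map(survivors, ~ desc[.x]),
    fitness = surv_fit,
    kxx = purrr::map_dbl(k_stats, "kxx"),
    delta_k = purrr::map_dbl(k_stats, "delta_k")
  )
  structure(
    list(
      candidates = candidates,
      best_model = fit_mlr(data, desc[survivors[[1]]], activity),
      model_size = p,
      config = config,
      history = history
    ),
    class = "ga_result"
  )
}

#' @export
print.ga_result <- function(x, ...) {
  cat("<ga_result>\n")
  cat(sprintf("  best %d-descriptor subset (%s fitness %.4f): %s\n",
              x$model_size, x$config$fitness, x$candidates$fitness[1],
              paste(x$candidates$descriptors[[1]], collapse = ", ")))
  cat(sprintf("  %d distinct surviving subsets\n", nrow(x$candidates)))
  invisible(x)
}

#' Build the one- to eight-variable model ladder
#'
#' Runs [ga_select()] once per requested subset size and assembles the best
#' model of each size together with its full [validation_report()] (external
#' block included when a test set is supplied). On the same data the
#' training fit can only improve as the subset grows, so training R2 is
#' non-decreasing along the ladder whenever the smaller optimum is reachable
#' from the larger search space.
#'
#' @param train Training tibble (descriptors + activity).
#' @param test Optional external test tibble.
#' @param sizes Integer vector of subset sizes. Default `1:8`.
#' @param config A [ga_config()]; each size runs with a seed offset so the
#'   searches are independent but reproducible.
#' @param activity Name of the activity column.
#' @return An object of class `model_ladder`: a list with `models` (named
#'   list of the per-size best [fit_mlr()] models), `statistics` (tibble,
#'   one row per size, conventional QSAR report labels plus `r_tr`/`r_ext`)
#'   and `ga_results`.
#' @export
build_model_ladder <- function(train, test = NULL, sizes = 1:8,
                               config = ga_config(), activity = "teac") {
  results <- list()
  stats <- list()
  for (p in sizes) {
    cfg <- config
    cfg$seed <- config$seed + p
    res <- ga_select(train, p, cfg, activity)
    rep <- validation_report(res$best_model, test)
    rep <- dplyr::bind_cols(tibble(model_size = p), rep)
    rep$r_tr <- sqrt(rep$R2)
    if ("R2_ext" %in% names(rep)) rep$r_ext <- sqrt(rep$R2_ext)
    results[[as.character(p)]] <- res
    stats[[as.character(p)]] <- rep
  }
  structure(
    list(
      models = purrr::map(results, "best_model"),
      statistics = dplyr::bind_rows(stats),
      ga_results = results
    ),
    class = "model_ladder"
  )
}

#' @export
print.model_ladder <- function(x, ...) {
  cat("<model_ladder>\n")
  cols <- intersect(c("model_size", "R2", "Q2_LOO", "R2_ext"), names(x$statistics))
  print(as.data.frame(x$statistics[cols]), row.names = FALSE, digits = 3)
  invisible(x)
}
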