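#' Run the full TEAC-QSAR modelling workflow
#'
#' End-to-end pipeline over a descriptor/activity table: degenerate-
#' descriptor filtering, rational activity-ranked train/test split, min-max
#' normalization learned on the training rows, GA-MLR subset selection with
#' QUIK filtering for every requested model size, the full validation report
#' per size, and the Williams applicability-domain report for the best
#' model. All artifacts are written to `out_dir` as CSV/JSON plus a plain-
#' text run log carrying the seed and a configuration hash, so a run is
#' reproducible from its archived configuration alone.
#'
#' @param input A descriptor tibble with `compound_id` and activity columns,
#'   or the path of a CSV in the layout of [write_descriptor_table()].
#' @param out_dir Output directory (created if needed).
#' @param n_test Number of test compounds for the rational split.
#' @param sizes Model sizes to build. Default `1:8`.
#' @param config A [ga_config()].
#' @param variance_tol,pair_r_max Passed to [filter_descriptors()].
#' @param lmo_fraction,lmo_iterations Leave-many-out settings for the best
#'   model's report.
#' @param n_scramble Y-scrambling permutations for the best model.
#' @param activity Name of the activity column. Default `"teac"`.
#' @param seed Integer seed overriding `config$seed`; every random stage
#'   (split tie-breaks, GA, LMO, scrambling) derives from it.
#' @return Invisibly, a list with `ladder`, `best_size`, `williams`,
#'   `lmo`, `scramble`, `acceptability` and `files` (paths written).
#' @export
run_pipeline <- function(input, out_dir, n_test = 14, sizes = 1:8,
                         config = ga_config(),
                         variance_tol = 1e-10, pair_r_max = 0.95,
                         lmo_fraction = 0.3, lmo_iterations = 100,
                         n_scramble = 100,
                         activity = "teac", seed = 1L) {
  data <- if (is.character(input)) read_descriptor_table(input) else input
  stopifnot(is.data.frame(data))
  if (!activity %in% names(data)) {
    abort(sprintf("activity column '%s' not found in the input table.", activity))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  config$seed <- check_count(seed, "seed", min = -.Machine$integer.max)

  log_lines <- character()
  note <- function(fmt, ...) {
    line <- sprintf("%s  %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                    sprintf(fmt, ...))
    log_lines <<- c(log_lines, line)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)))
    })
  }

  cfg_hash <- rlang::hash(list(n_test = n_test, sizes = sizes, config = config,
                               variance_tol = variance_tol,
                               pair_r_max = pair_r_max,
                               lmo = c(lmo_fraction, lmo_iterations),
                               n_scramble = n_scramble, activity = activity))
  note("run start (seed %d, config hash %s)", config$seed, cfg_hash)

  filtered <- run_stage("filter", filter_descriptors(
    data, variance_tol = variance_tol, pair_r_max = pair_r_max,
    activity = activity))
  note("filter: %d descriptors kept, %d removed",
       length(descriptor_columns(filtered, activity)),
       nrow(removal_log(filtered)))

  split <- run_stage("split", rational_split(filtered, n_test,
                                             activity = activity,
                                             seed = config$seed))
  normalized <- run_stage("normalize", normalize_descriptors(split,
                                                             activity = activity))
  train <- normalized[normalized$.set == "train", , drop = FALSE]
  test <- normalized[normalized$.set == "test", , drop = FALSE]
  note("split: %d train / %d test", nrow(train), nrow(test))

  ladder <- run_stage("ga_mlr", build_model_ladder(
    train, test, sizes = sizes, config = config, activity = activity))

  best_row <- which.max(ladder$statistics$Q2_LOO)
  best_size <- ladder$statistics$model_size[best_row]
  best <- ladder$models[[as.character(best_size)]]
  note("best model by Q2_LOO: %d descriptors (%s)", best_size,
       paste(best$descriptor_names, collapse = ", "))

  lmo <- run_stage("lmo", lmo_cv(best, lmo_fraction, lmo_iterations,
                                 seed = config$seed))
  scr <- run_stage("y_scramble", y_scramble(best, n_scramble,
                                            seed = config$seed))
  accept <- acceptability_check(fit_statistics(best), loo_cv(best),
                                external_validation(best, test), scr)
  williams <- run_stage("applicability_domain", williams_report(best, test))

  # --- artifacts
  stats_out <- dplyr::mutate(ladder$statistics, config_hash = cfg_hash)
  f_stats <- file.path(out_dir, "ladder_statistics.csv")
  readr::write_csv(stats_out, f_stats)

  f_models <- file.path(out_dir, "models.json")
  jsonlite::write_json(
    purrr::map(ladder$models, function(m) {
      list(descriptors = m$descriptor_names,
           coefficients = as.list(m$coefficients),
           coefficient_ses = as.list(m$coefficient_ses),
           intercept = m$intercept, intercept_se = m$intercept_se,
           n_train = m$n_train)
    }),
    f_models, auto_unbox = TRUE, digits = NA)

  f_validation <- file.path(out_dir, "validation.json")
  jsonlite::write_json(
    list(config_hash = cfg_hash,
         ladder = purrr::transpose(as.list(ladder$statistics)),
         best_model = list(size = best_size,
                           q2_lmo = lmo$q2_lmo,
                           scramble_mean_r2 = scr$mean_r2,
                           scramble_mean_q2 = scr$mean_q2,
                           acceptability = as.list(accept))),
    f_validation, auto_unbox = TRUE, digits = NA)

  f_ad <- file.path(out_dir, "applicability_domain.csv")
  ad_out <- dplyr::mutate(tibble::as_tibble(williams), config_hash = cfg_hash)
  readr::write_csv(ad_out, f_ad)

  f_log <- file.path(out_dir, "run_log.txt")
  note("run complete")
  writeLines(log_lines, f_log)

  invisible(list(
    ladder = ladder, best_size = best_size, williams = williams,
    lmo = lmo, scramble = scr, acceptability = accept,
    config_hash = cfg_hash,
    files = c(statistics = f_stats, models = f_models,
              validation = f_validation, ad = f_ad, log = f_log)
  ))
}
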