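#' Reference panel of 82 pharmaceuticals with measured TEAC values
#'
#' Loads the packaged screening panel: 82 frequently prescribed drugs with
#' their CAS numbers, molecular formulas, pharmacologic classes, ATC group
#' letters and the TEAC value (mM) determined by the HPLC-DPPH assay.
#' Compounds whose scavenging fell below the quantifiable range carry the
#' token value 0.00001 mM.
#'
#' @return A tibble with 82 rows and columns `name`, `cas`,
#'   `molecular_formula`, `pharmacologic_class`, `atc`, `teac`.
#' @export
load_drug_panel <- function() {
  path <- system.file("extdata", "drug_teac_panel.csv", package = "teacqsar",
                      mustWork = TRUE)
  panel <- readr::read_csv(path, show_col_types = FALSE,
                           col_types = readr::cols(
                             cas = readr::col_character(),
                             teac = readr::col_double(),
                             .default = readr::col_character()
                           ))
  if (nrow(panel) != 82 || anyNA(panel$teac) || any(panel$teac < 0)) {
    abort("packaged drug panel is corrupted.")
  }
  panel
}

#' Classify TEAC values into activity bands
#'
#' Three-band interpretation of antioxidant strength: `low` below the lower
#' cutoff, `mid` within the closed interval `[low_cut, high_cut]`, `high`
#' above it. The defaults (0.100 and 0.200 mM) are the screening cutoffs
#' separating negligible, measurable and strong radical-scavenging activity;
#' both boundaries belong to the middle band.
#'
#' @param teac Numeric vector of TEAC values (mM), non-negative.
#' @param low_cut,high_cut Band boundaries in mM.
#' @return A factor with levels `low`, `mid`, `high`.
#' @export
classify_band <- function(teac, low_cut = 0.100, high_cut = 0.200) {
  if (any(teac < 0, na.rm = TRUE)) abort("TEAC values must be non-negative.")
  factor(
    dplyr::case_when(
      teac < low_cut ~ "low",
      teac <= high_cut ~ "mid",
      TRUE ~ "high"
    ),
    levels = c("low", "mid", "high")
  )
}

#' Band counts and percentages for a compound panel
#'
#' Tabulates [classify_band()] over a panel and reports counts and
#' whole-number percentages per band, plus the share of compounds at or
#' above the lower cutoff (the "measurable activity" fraction).
#'
#' @param data Data frame with a TEAC column.
#' @param activity Name of the TEAC column (default `"teac"`).
#' @inheritParams classify_band
#' @return A tibble with one row per band (`band`, `n`, `percent`) carrying
#'   the attribute `percent_active` (percent of compounds in the mid or high
#'   band, rounded to a whole number).
#' @export
band_summary <- function(data, activity = "teac",
                         low_cut = 0.100, high_cut = 0.200) {
  stopifnot(is.data.frame(data))
  if (nrow(data) == 0) abort("`data` is empty.")
  if (!activity %in% names(data)) abort(sprintf("column '%s' not found.", activity))
  bands <- classify_band(data[[activity]], low_cut, high_cut)
  out <- tibble(band = factor(c("low", "mid", "high"),
                              levels = c("low", "mid", "high"))) |>
    dplyr::left_join(
      tibble(band = bands) |> dplyr::count(.data$band),
      by = "band"
    ) |>
    dplyr::mutate(
      n = dplyr::coalesce(.data$n, 0L),
      percent = round(100 * .data$n / length(bands))
    )
  attr(out, "percent_active") <- round(100 * sum(bands != "low") / length(bands))
  out
}

#' Remove degenerate and redundant descriptors
#'
#' Pre-reduction ahead of subset selection: drops constant or near-constant
#' columns (variance at or below `variance_tol`) and, scanning column pairs
#' left to right, the later member of any pair whose absolute Pearson
#' correlation is at least `pair_r_max`.
#'
#' @param data Descriptor tibble (identifier and activity columns are left
#'   untouched).
#' @param variance_tol Variance at or below which a column counts as
#'   constant. Default `1e-10`.
#' @param pair_r_max Absolute correlation at or above which the later column
#'   of a pair is dropped. Default `0.95`.
#' @param activity Name of the activity column to protect (default `"teac"`).
#' @return The reduced tibble, with a `removal_log` attribute: a tibble of
#'   dropped columns, the reason, and for correlation removals the partner
#'   column and the offending r. Use [removal_log()] to retrieve it.
#' @export
filter_descriptors <- function(data, variance_tol = 1e-10, pair_r_max = 0.95,
                               activity = "teac") {
  stopifnot(is.data.frame(data))
  desc <- descriptor_columns(data, activity)
  if (length(desc) == 0) abort("no descriptor columns to filter.")
  x <- as.matrix(data[desc])

  vars <- apply(x, 2, var)
  const <- desc[vars <= variance_tol]
  log <- tibble(column = const, reason = rep("near_constant", length(const)),
                partner = NA_character_, r = NA_real_)

  keep <- setdiff(desc, const)
  if (length(keep) >= 2) {
    cx <- suppressWarnings(cor(x[, keep, drop = FALSE]))
    dropped <- character()
    for (j in seq_along(keep)[-1]) {
      earlier <- setdiff(keep[seq_len(j - 1)], dropped)
      if (length(earlier) == 0) next
      r_with <- abs(cx[earlier, keep[j]])
      hit <- which(r_with >= pair_r_max)
      if (length(hit) > 0) {
        dropped <- c(dropped, keep[j])
        log <- dplyr::bind_rows(log, tibble(
          column = keep[j], reason = "high_correlation",
          partner = earlier[hit[1]], r = unname(cx[earlier[hit[1]], keep[j]])
        ))
      }
    }
    keep <- setdiff(keep, dropped)
  }
  if (length(keep) == 0) abort("all descriptor columns were removed.")
  out <- data[c(intersect(c("compound_id"), names(data)), keep,
                intersect(activity, names(data)),
                intersect(".set", names(data)))]
  attr(out, "removal_log") <- log
  out
}

#' @rdname filter_descriptors
#' @param x A tibble returned by [filter_descriptors()].
#' @export
removal_log <- function(x) attr(x, "removal_log")

#' Min-max normalize descriptors against the training set
#'
#' Maps every descriptor to `(value - min) / (max - min)` using the minimum
#' and maximum *learned from the training rows only*, so that training
#' values lie in `[0, 1]` while test values may fall outside (they are kept
#' and flagged, not truncated). Models fitted on normalized descriptors have
#' directly comparable coefficient magnitudes.
#'
#' @param data Descriptor tibble. If it has a `.set` column (see
#'   [rational_split()]) the rows with `.set == "train"` define the ranges;
#'   otherwise all rows do.
#' @param params Optional normalization parameters from a previous call (the
#'   `norm_params` attribute), applied as-is. Default `NULL` learns them.
#' @param activity Name of the activity column (left untouched).
#' @return The normalized tibble with attributes `norm_params` (tibble of
#'   per-descriptor min/max) and `out_of_range` (logical matrix marking
#'   values outside `[0, 1]`). Use [norm_params()] to retrieve the ranges.
#' @export
normalize_descriptors <- function(data, params = NULL, activity = "teac") {
  stopifnot(is.data.frame(data))
  desc <- descriptor_columns(data, activity)
  if (is.null(params)) {
    train_rows <- if (".set" %in% names(data)) data$.set == "train" else
      rep(TRUE, nrow(data))
    if (!any(train_rows)) abort("no training rows to learn ranges from.")
    params <- tibble(
      descriptor = desc,
      min = unname(vapply(data[desc], function(v) min(v[train_rows]), numeric(1))),
      max = unname(vapply(data[desc], function(v) max(v[train_rows]), numeric(1)))
    )
  }
  stopifnot(all(c("descriptor", "min", "max") %in% names(params)))
  missing <- setdiff(desc, params$descriptor)
  if (length(missing) > 0) {
    abort(paste0("no normalization parameters for: ",
                 paste(missing, collapse = ", ")))
  }
  out <- data
  oor <- matrix(FALSE, nrow(data), length(desc), dimnames = list(NULL, desc))
  for (nm in desc) {
    p <- params[params$descriptor == nm, ]
    if (p$max == p$min) {
      abort(sprintf("descriptor '%s' has zero range; filter it first.", nm))
    }
    z <- (data[[nm]] - p$min) / (p$max - p$min)
    out[[nm]] <- z
    oor[, nm] <- z < 0 | z > 1
  }
  attr(out, "norm_params") <- params
  attr(out, "out_of_range") <- oor
  out
}

#' @rdname normalize_descriptors
#' @param x A tibble returned by [normalize_descriptors()].
#' @export
norm_params <- function(x) attr(x, "norm_params")

#' Rational activity-ranked train/test split
#'
#' Splits compounds so the test set covers the whole activity range while
#' prediction stays interpolative: compounds are ranked by activity, the
#' minimum and maximum are forced into the training set, the remaining ranks
#' are cut into `n_test` equal-width rank bins, and the middle compound of
#' each bin goes to the test set. The assignment is deterministic; the seed
#' is used only to break exact ties in activity.
#'
#' @param data Data frame of compounds.
#' @param n_test Number of test compounds (at most a third of the rows).
#' @param activity Name of the activity column (default `"teac"`).
#' @param seed Integer seed for tie-breaking.
#' @return `data` with an added `.set` factor column (`train`/`test`).
#' @export
rational_split <- function(data, n_test, activity = "teac", seed = 1L) {
  stopifnot(is.data.frame(data))
  if (!activity %in% names(data)) abort(sprintf("column '%s' not found.", activity))
  n <- nrow(data)
  n_test <- check_count(n_test, "n_test", min = 1L)
  if (n_test > n / 3) abort("`n_test` must not exceed a third of the compounds.")
  y <- data[[activity]]
  tie_break <- with_seed(seed, runif(n))
  ord <- order(y, tie_break)

  set <- rep("train", n)
  inner <- ord[-c(1L, n)]           # extremes stay in training
  n_inner <- length(inner)
  # equal-width rank bins; middle element of each bin is the test compound
  bounds <- round(seq(0, n_inner, length.out = n_test + 1L))
  for (b in seq_len(n_test)) {
    lo <- bounds[b] + 1L
    hi <- bounds[b + 1L]
    if (hi < lo) next
    mid <- lo + (hi - lo) %/% 2L
    set[inner[mid]] <- "test"
  }
  out <- data
  out$.set <- factor(set, levels = c("train", "test"))
  out
}
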