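# Cached fixture readers ----------------------------------------------------

the_fixture_env <- new.env(parent = emptyenv())

read_models_fixture <- function() {
  if (is.null(the_fixture_env$models)) {
    path <- system.file("extdata", "teac_models.json", package = "teacqsar",
                        mustWork = TRUE)
    the_fixture_env$models <- jsonlite::fromJSON(path, simplifyVector = FALSE)$models
  }
  the_fixture_env$models
}

read_descriptor_fixture <- function() {
  if (is.null(the_fixture_env$descriptors)) {
    path <- system.file("extdata", "descriptor_info.json", package = "teacqsar",
                        mustWork = TRUE)
    raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)$descriptors
    the_fixture_env$descriptors <- purrr::map_dfr(raw, function(d) {
      tibble(
        name = d$name,
        definition = d$definition,
        family = d$family,
        models = list(unlist(d$models)),
        note = d$note %||% NA_character_
      )
    })
  }
  the_fixture_env$descriptors
}

#' Retrieve one of the eight fixed TEAC regression equations
#'
#' The package ships eight pre-fitted linear TEAC models (one to eight
#' descriptors) as fixed predictors. Model `k` has exactly `k` terms; the
#' coefficients apply to descriptors normalized with the original training
#' set's min-max ranges, which are not distributed, so these equations are
#' meant for normalized inputs only.
#'
#' @param model_id Integer in 1..8.
#' @return An object of class `published_model`: a list with `model_id`,
#'   `terms` (tibble of `descriptor`, `coefficient`, `uncertainty` — the
#'   printed +/- value, read as one standard error), `intercept` and
#'   `intercept_uncertainty` (mM).
#' @export
published_model <- function(model_id) {
  if (!is.numeric(model_id) || length(model_id) != 1L || is.na(model_id) ||
      model_id != floor(model_id) || model_id < 1 || model_id > 8) {
    abort("`model_id` must be in 1..8.")
  }
  model_id <- as.integer(model_id)
  raw <- read_models_fixture()[[model_id]]
  stopifnot(raw$model_id == model_id)
  structure(
    list(
      model_id = model_id,
      terms = purrr::map_dfr(raw$terms, tibble::as_tibble),
      intercept = raw$intercept,
      intercept_uncertainty = raw$intercept_uncertainty
    ),
    class = "published_model"
  )
}

#' @export
print.published_model <- function(x, ...) {
  cat(sprintf("<published_model %d>\n", x$model_id))
  terms <- paste(sprintf("%+.4f(±%.4f) x %s", x$terms$coefficient,
                         x$terms$uncertainty, x$terms$descriptor),
                 collapse = " ")
  cat(sprintf("  TEAC = %s %+.4f(±%.4f)\n", terms, x$intercept,
              x$intercept_uncertainty))
  invisible(x)
}

#' All fixed TEAC equations as one tidy table
#'
#' @return A tibble with one row per model term: `model_id`, `descriptor`,
#'   `coefficient`, `uncertainty`, `intercept`, `intercept_uncertainty`.
#' @export
published_models <- function() {
  purrr::map_dfr(1:8, function(id) {
    m <- published_model(id)
    dplyr::bind_cols(tibble(model_id = id), m$terms,
                     tibble(intercept = m$intercept,
                            intercept_uncertainty = m$intercept_uncertainty))
  })
}

#' Predict TEAC with a fixed equation
#'
#' Evaluates `intercept + sum(coefficient * value)` for one of the fixed
#' models. Inputs must already be normalized to the original training
#' ranges; raw descriptor values are not supported because the normalization
#' constants were never published. Values outside `[0, 1]` are accepted but
#' flagged as extrapolation, and negative predictions are returned as-is
#' with a warning flag rather than clamped (the equation is linear, and
#' clamping would hide extrapolation).
#'
#' @param model_id Integer in 1..8.
#' @param values A named numeric vector, or a data frame with one column per
#'   model descriptor (one prediction per row).
#' @return A tibble with columns `teac` (mM), `out_of_unit_range` and
#'   `negative_prediction`.
#' @export
predict_teac <- function(model_id, values) {
  m <- published_model(model_id)
  if (is.numeric(values) && !is.null(names(values))) {
    values <- tibble::as_tibble(as.list(values))
  }
  stopifnot(is.data.frame(values))
  missing <- setdiff(m$terms$descriptor, names(values))
  if (length(missing) > 0) {
    abort(paste0("missing descriptor value(s): ", paste(missing, collapse = ", ")))
  }
  x <- as.matrix(values[m$terms$descriptor])
  pred <- drop(m$intercept + x %*% m$terms$coefficient)
  tibble(
    teac = pred,
    out_of_unit_range = apply(x < 0 | x > 1, 1, any),
    negative_prediction = pred < 0
  )
}

#' Descriptor metadata
#'
#' Name, plain-text definition and family of every molecular descriptor
#' used by the fixed TEAC equations.
#'
#' @param name Optional descriptor name; `NULL` returns the whole table.
#' @return A tibble with columns `name`, `definition`, `family`, `models`
#'   (list of model sizes using the descriptor) and `note`.
#' @export
describe_descriptor <- function(name = NULL) {
  info <- read_descriptor_fixture()
  if (is.null(name)) return(info)
  hit <- info[info$name == name, ]
  if (nrow(hit) == 0) abort(sprintf("unknown descriptor '%s'.", name))
  hit
}

#' Coefficient signs of a fixed equation
#'
#' Per-term sign with a plain interpretation tag: a positive coefficient
#' means larger (normalized) descriptor values increase the predicted
#' TEAC, a negative one means they depress it.
#'
#' @param model_id Integer in 1..8.
#' @return A tibble with columns `descriptor`, `coefficient`, `sign` and
#'   `effect`.
#' @export
coefficient_sign_summary <- function(model_id) {
  m <- published_model(model_id)
  m$terms |>
    dplyr::transmute(
      descriptor = .data$descriptor,
      coefficient = .data$coefficient,
      sign = ifelse(.data$coefficient >= 0, "positive", "negative"),
      effect = ifelse(.data$coefficient >= 0,
                      "increases predicted TEAC",
                      "decreases predicted TEAC")
    )
}
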