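#' The a priori candidate model set
#'
#' Fourteen candidate variable sets over reproductive condition, individual,
#' minimum ambient temperature, maximum wind speed, and precipitation --
#' single variables, the tabulated combinations, and the global model with
#' all five predictors -- applied identically to the three responses
#' (frequency, duration, depth).
#' Frequency is modeled as Bernoulli with a logit link; duration and depth
#' as Normal. Models containing reproductive condition and/or individual are
#' hierarchical: condition deflections draw from a common Normal, individual
#' deflections from a Normal within their condition.
#'
#' @param response One of `"frequency"`, `"duration"`, `"depth"`.
#' @return A tibble with one row per candidate: `model` (label), `response`,
#'   `family`, `hierarchical`, `n_vars`, and a list-column `spec` of
#'   [model_spec()] objects.
#' @examples
#' candidate_models("frequency")$model
#' @export
candidate_models <- function(response = c("frequency", "duration", "depth")) {
  response <- match.arg(response)
  sets <- list(
    c("precip", "wind"),
    c("precip"),
    c("precip", "wind", "reproductive", "min_ta"),
    c("wind"),
    c("precip", "wind", "min_ta", "individual"),
    c("precip", "reproductive", "individual"),
    c("wind", "min_ta"),
    c("min_ta"),
    c("individual"),
    c("reproductive"),
    c("reproductive", "individual"),
    c("reproductive", "individual", "min_ta"),
    c("reproductive", "individual", "wind"),
    # the global model closes the set: all five predictors together
    c("reproductive", "individual", "min_ta", "wind", "precip")
  )
  specs <- map(sets, ~ model_spec(response, .x))
  tibble(
    model = map_chr(specs, "label"),
    response = response,
    family = map_chr(specs, "family"),
    hierarchical = map_lgl(specs, "hierarchical"),
    n_vars = lengths(sets),
    spec = specs
  )
}

#' Define a single candidate model
#'
#' @param response `"frequency"` (Bernoulli-logit), `"duration"` or
#'   `"depth"` (Normal).
#' @param variables Subset of `reproductive`, `individual`, `min_ta`,
#'   `wind`, `precip`.
#' @return A list of class `"torpor_model_spec"` with fields `response`,
#'   `family`, `variables`, `hierarchical`, `label`.
#' @export
model_spec <- function(response = c("frequency", "duration", "depth"),
                       variables) {
  response <- match.arg(response)
  allowed <- c("reproductive", "individual", "min_ta", "wind", "precip")
  variables <- unique(variables)
  if (!all(variables %in% allowed)) {
    abort(sprintf(
      "Unknown variable(s): %s",
      paste(setdiff(variables, allowed), collapse = ", ")
    ))
  }
  pretty <- c(
    reproductive = "Reproductive", individual = "Individual",
    min_ta = "Min Ta", wind = "Wind", precip = "Precipitation"
  )
  # the label preserves the order the variables were given in, matching the
  # conventional table layout (weather-led for frequency rows, condition-led
  # for duration/depth rows)
  ord <- variables
  structure(
    list(
      response = response,
      family = if (response == "frequency") "bernoulli" else "normal",
      variables = variables,
      hierarchical = any(c("reproductive", "individual") %in% variables),
      label = paste(pretty[ord], collapse = " + ")
    ),
    class = "torpor_model_spec"
  )
}

#' @export
print.torpor_model_spec <- function(x, ...) {
  cat(sprintf(
    "<torpor_model_spec> %s ~ %s [%s%s]\n",
    x$response, x$label, x$family, if (x$hierarchical) ", hierarchical" else ""
  ))
  invisible(x)
}
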