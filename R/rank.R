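#' Rank candidate models by DIC
#'
#' Computes, for each candidate, the DIC difference from the best model
#' (`delta = dic - min(dic)`), the DIC weight
#' `w = exp(-delta/2) / sum(exp(-delta/2))` (the Akaike-weight form, read as
#' the likelihood that the model is the best of the set), and the cumulative
#' weight down the ranking, flagging the smallest top set holding at least
#' `level` of the weight. DIC ties are broken by fewer variables, then by
#' label, so tables are deterministic.
#'
#' @param fits A list of [sample_posterior()] fits for one response, or a
#'   data frame with columns `model` and `dic` (and optionally `n_vars`,
#'   `weight`). Supplying `weight` directly (e.g. re-analyzing a published
#'   table printed to 2 decimals) skips the `exp(-delta/2)` computation.
#' @param level Confidence-set level (default 0.95).
#' @param renormalize When weights are supplied directly, rescale them to
#'   sum to 1 (`TRUE`, default). Use `FALSE` for weights that are already
#'   normalized over a larger candidate set than the rows given (e.g. a
#'   published table that prints only the confidence set), so cumulative
#'   weights keep their original meaning.
#' @return A tibble of class `"torpor_rank_table"`, sorted by DIC: `model`,
#'   `response`, `n_vars`, `dic`, `delta`, `weight`, `cum_weight`,
#'   `in_conf_set`, plus a list-column `fit` when fits were supplied.
#' @examples
#' rank_models(tibble::tibble(model = c("A", "B"), dic = c(10, 12)))
#' @export
rank_models <- function(fits, level = 0.95, renormalize = TRUE) {
  if (is.data.frame(fits)) {
    tbl <- as_tibble(fits)
    if (!"n_vars" %in% names(tbl)) tbl$n_vars <- NA_integer_
    if (!"response" %in% names(tbl)) tbl$response <- NA_character_
    if (!"variables" %in% names(tbl)) {
      tbl$variables <- map(tbl$model, label_to_variables)
    }
  } else {
    stopifnot(all(map_lgl(fits, inherits, "torpor_fit")))
    responses <- unique(map_chr(fits, ~ .x$spec$response))
    if (length(responses) != 1) {
      abort("All fits must share one response; got: " %+%
        paste(responses, collapse = ", "))
    }
    tbl <- tibble(
      model = map_chr(fits, ~ .x$spec$label),
      response = responses,
      n_vars = purrr::map_int(fits, ~ length(.x$spec$variables)),
      variables = map(fits, ~ .x$spec$variables),
      dic = map_dbl(fits, "dic"),
      fit = fits
    )
  }

  if ("weight" %in% names(tbl)) {
    if (renormalize) tbl <- tbl |> mutate(weight = .data$weight / sum(.data$weight))
    if (!"dic" %in% names(tbl)) tbl$dic <- NA_real_
    if (!"delta" %in% names(tbl)) tbl$delta <- NA_real_
    tbl <- tbl |> arrange(dplyr::desc(.data$weight), .data$n_vars, .data$model)
  } else {
    tbl <- tbl |>
      mutate(
        delta = .data$dic - min(.data$dic),
        weight = exp(-.data$delta / 2) / sum(exp(-.data$delta / 2))
      ) |>
      arrange(.data$dic, .data$n_vars, .data$model)
  }

  tbl <- tbl |>
    mutate(
      cum_weight = cumsum(.data$weight),
      # smallest top-ranked prefix reaching the level
      in_conf_set = dplyr::lag(.data$cum_weight, default = 0) < level
    ) |>
    relocate(dplyr::any_of(c(
      "model", "response", "n_vars", "dic", "delta", "weight", "cum_weight",
      "in_conf_set"
    )))
  class(tbl) <- c("torpor_rank_table", class(tbl))
  attr(tbl, "level") <- level
  tbl
}

`%+%` <- function(a, b) paste0(a, b)

# invert the pretty model labels back to variable names
label_to_variables <- function(label) {
  lut <- c(
    Reproductive = "reproductive", Individual = "individual",
    "Min Ta" = "min_ta", Wind = "wind", Precipitation = "precip"
  )
  parts <- trimws(strsplit(label, "+", fixed = TRUE)[[1]])
  out <- unname(lut[parts])
  # labels outside the standard vocabulary are kept verbatim
  ifelse(is.na(out), parts, out)
}

#' Extract the confidence set of a rank table
#'
#' The smallest set of top-ranked models whose cumulative DIC weight reaches
#' `level` (by construction it always includes the top model).
#'
#' @param rank_table A [rank_models()] table.
#' @param level Weight level (defaults to the table's own).
#' @return The confidence-set rows (still a `torpor_rank_table`).
#' @export
confidence_set <- function(rank_table, level = attr(rank_table, "level") %||% 0.95) {
  keep <- dplyr::lag(cumsum(rank_table$weight), default = 0) < level
  out <- rank_table[keep, ]
  attr(out, "level") <- level
  out
}

#' Normalized variable weights
#'
#' For each predictor variable, the summed weight of the confidence-set
#' models containing it, normalized by the total weight of the set. A
#' normalized weight above `threshold` (default 0.60) flags the variable as
#' having explanatory effects.
#'
#' @param conf_set A confidence set from [confidence_set()] (or a full rank
#'   table, in which case the set is taken at its level first).
#' @param variables Variables to score (defaults to the five candidates).
#' @param threshold Explanatory flag threshold.
#' @return A tibble `variable`, `norm_weight`, `explanatory`.
#' @export
variable_weights <- function(conf_set,
                             variables = c(
                               "reproductive", "individual", "min_ta",
                               "wind", "precip"
                             ),
                             threshold = 0.60) {
  if (!all(conf_set$in_conf_set)) conf_set <- confidence_set(conf_set)
  if (nrow(conf_set) == 0) abort("Empty confidence set.")
  total <- sum(conf_set$weight)
  tibble(
    variable = variables,
    norm_weight = map_dbl(variables, function(v) {
      has <- map_lgl(conf_set$variables, ~ v %in% .x)
      sum(conf_set$weight[has]) / total
    })
  ) |>
    mutate(explanatory = .data$norm_weight > threshold)
}
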