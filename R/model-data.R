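#' Assemble centered design data for one candidate model
#'
#' Joins daily weather onto the bat-day table, selects the response implied
#' by the model spec, centers each included continuous covariate at its
#' sample mean (so intercepts are interpretable as the mean response), and
#' encodes reproductive-condition and individual indices.
#'
#' @param bat_days Daily torpor table (from [extract_torpor_metrics()] or
#'   [read_bat_days_csv()]).
#' @param weather Daily weather tibble (`date`, `max_wind_kmh`, `precip_mm`,
#'   `min_ta`).
#' @param spec A [model_spec()].
#' @return A list of class `"torpor_model_data"`: response vector `y`,
#'   centered covariate matrix `X` (zero columns when the model has no
#'   continuous variables), covariate means `centers`, condition/individual
#'   index vectors and levels, and the model spec itself.
#' @export
build_model_data <- function(bat_days, weather, spec) {
  stopifnot(inherits(spec, "torpor_model_spec"))
  missing_dates <- setdiff(as.character(bat_days$date), as.character(weather$date))
  if (length(missing_dates)) {
    abort(sprintf(
      "Weather is missing date(s) present in the bat-day table: %s",
      paste(missing_dates, collapse = ", ")
    ))
  }
  df <- bat_days |>
    left_join(weather, by = "date")

  y <- switch(spec$response,
    frequency = as.numeric(df$torpid),
    duration = df$duration_min,
    depth = df$depth_c
  )

  cols <- c(min_ta = "min_ta", wind = "max_wind_kmh", precip = "precip_mm")
  cont <- intersect(c("min_ta", "wind", "precip"), spec$variables)
  X <- matrix(0, nrow(df), length(cont), dimnames = list(NULL, cont))
  centers <- setNames(numeric(length(cont)), cont)
  for (v in cont) {
    raw <- df[[cols[[v]]]]
    centers[[v]] <- mean(raw)
    X[, v] <- raw - centers[[v]]
  }

  cond_levels <- ind_levels <- NULL
  cond_idx <- ind_idx <- NULL
  ind_cond <- NULL
  if ("reproductive" %in% spec$variables) {
    cond_levels <- intersect(condition_labels(), unique(df$condition))
    cond_idx <- match(df$condition, cond_levels)
  }
  if ("individual" %in% spec$variables) {
    ind_levels <- sort(unique(df$individual_id))
    ind_idx <- match(df$individual_id, ind_levels)
    ind_cond <- df$condition[match(ind_levels, df$individual_id)]
  }

  structure(
    list(
      y = y, X = X, centers = centers,
      cond_idx = cond_idx, cond_levels = cond_levels,
      ind_idx = ind_idx, ind_levels = ind_levels, ind_cond = ind_cond,
      n = length(y), family = spec$family, spec = spec
    ),
    class = "torpor_model_data"
  )
}

#' @export
print.torpor_model_data <- function(x, ...) {
  cat(sprintf(
    "<torpor_model_data> %s ~ %s: n = %d, %d covariate(s), %d condition(s), %d individual(s)\n",
    x$spec$response, x$spec$label, x$n, ncol(x$X),
    length(x$cond_levels), length(x$ind_levels)
  ))
  invisible(x)
}
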