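#' Model-averaged estimate with unconditional SD
#'
#' Averages a parameter over the confidence-set models that contain it,
#' with weights renormalized over those models ("natural averaging" -- no
#' zero substitution, so parameters existing only in hierarchical models are
#' averaged over those). The point estimate is
#' `theta_hat = sum w'_i * theta_i` (posterior means on the reporting
#' scale); the unconditional SD follows the Burnham-Anderson form
#' `sd_u = sum w'_i * sqrt(var_i + (theta_i - theta_hat)^2)`, which folds
#' model-selection uncertainty into the within-model posterior variance.
#' The 95% HDI is taken from the highest-ranked containing model's draws,
#' and `beta0_avg` is the intercept averaged over the same containing set.
#'
#' @param rank_table A [rank_models()] table carrying a `fit` list-column.
#' @param parameter Reported parameter name: a slope (`"wind"`, `"precip"`,
#'   `"min_ta"`), a condition deflection (`"cond:P"`, ...), an individual
#'   deflection (`"ind:<id>"`), or `"beta0"`.
#' @param level Confidence-set level.
#' @param hdi_mass Mass of the reported HDI.
#' @return A one-row tibble: `parameter`, `estimate`, `sd_u`, `hdi_lo`,
#'   `hdi_hi`, `beta0_avg`, `n_models`, `top_model`.
#' @export
model_average <- function(rank_table, parameter, level = 0.95,
                          hdi_mass = 0.95) {
  if (!"fit" %in% names(rank_table)) {
    abort("`rank_table` must carry fitted models (build it from fits).")
  }
  conf <- confidence_set(rank_table, level)
  rep_draws <- map(conf$fit, reported_samples)
  has <- map_lgl(rep_draws, ~ parameter %in% colnames(.x))
  if (!any(has)) {
    abort(sprintf("Parameter `%s` is absent from every confidence-set model.", parameter))
  }
  w <- conf$weight[has] / sum(conf$weight[has])
  draws <- rep_draws[has]
  means <- map_dbl(draws, ~ mean(.x[, parameter]))
  vars <- map_dbl(draws, ~ var(.x[, parameter]))
  theta_hat <- sum(w * means)
  sd_u <- sum(w * sqrt(vars + (means - theta_hat)^2))
  beta0s <- map_dbl(draws, ~ mean(.x[, "beta0"]))
  h <- hdi(draws[[1]][, parameter], mass = hdi_mass)
  tibble(
    parameter = parameter,
    estimate = theta_hat,
    sd_u = sd_u,
    hdi_lo = h[["lower"]],
    hdi_hi = h[["upper"]],
    beta0_avg = sum(w * beta0s),
    n_models = sum(has),
    top_model = conf$model[has][1]
  )
}

#' Model-averaged estimates for all explanatory variables
#'
#' Convenience wrapper producing the averaged-estimates table: for every
#' variable whose normalized weight exceeds the threshold, each of its
#' reported parameters (the slope, or every condition/individual deflection)
#' is model-averaged over the confidence set.
#'
#' @inheritParams model_average
#' @param threshold Normalized-variable-weight cutoff (default 0.60).
#' @return A tibble with one row per reported parameter, plus a `variable`
#'   column.
#' @export
summarize_multimodel <- function(rank_table, level = 0.95, threshold = 0.60) {
  conf <- confidence_set(rank_table, level)
  vw <- variable_weights(conf, threshold = threshold)
  keep <- vw$variable[vw$explanatory]
  empty <- tibble(
    variable = character(), parameter = character(), estimate = double(),
    sd_u = double(), hdi_lo = double(), hdi_hi = double(),
    beta0_avg = double(), n_models = integer(), top_model = character()
  )
  if (length(keep) == 0) return(empty)
  rows <- purrr::map(keep, function(v) {
    pars <- switch(v,
      wind = "wind", precip = "precip", min_ta = "min_ta",
      reproductive = paste0("cond:", condition_labels()),
      individual = {
        ids <- unique(unlist(map(
          conf$fit,
          ~ .x$data$ind_levels %||% character()
        )))
        paste0("ind:", sort(ids))
      }
    )
    avail <- unique(unlist(map(conf$fit, ~ colnames(reported_samples(.x)))))
    pars <- intersect(pars, avail)
    list_rbind(map(pars, ~ model_average(rank_table, .x, level))) |>
      mutate(variable = v, .before = 1)
  })
  out <- list_rbind(rows)
  if (nrow(out) == 0) empty else out
}

#' Odds ratio for a log-odds estimate
#'
#' `exp(estimate * unit_increase)`: the multiplicative change in the odds of
#' daily torpor use for a `unit_increase` change in the covariate.
#'
#' @param estimate Posterior (model-averaged) log-odds slope.
#' @param unit_increase Covariate change the ratio refers to (e.g. 10 for a
#'   0-to-10 km/hr wind increase).
#' @return The odds ratio (vectorized).
#' @examples
#' odds_ratio(0.03, 10)
#' odds_ratio(0.31, 10)
#' @export
odds_ratio <- function(estimate, unit_increase = 1) {
  if (!all(is.finite(estimate)) || !all(is.finite(unit_increase))) {
    abort("`estimate` and `unit_increase` must be finite.")
  }
  exp(estimate * unit_increase)
}

#' Fitted effect curve from averaged estimates
#'
#' Points of the logistic response curve
#' `p(x) = ilogit(beta0 + slope * x)` (frequency models) or the line
#' `y = beta0 + slope * x` (duration/depth models), for plotting or CSV
#' export.
#'
#' @param beta0 Intercept on the modeled scale.
#' @param slope Covariate slope.
#' @param x Covariate grid.
#' @param family `"bernoulli"` or `"normal"`.
#' @return Tibble `x`, `y`.
#' @export
effect_curve <- function(beta0, slope, x = seq(0, 50, by = 0.5),
                         family = c("bernoulli", "normal")) {
  family <- match.arg(family)
  eta <- beta0 + slope * x
  tibble(x = x, y = if (family == "bernoulli") ilogit(eta) else eta)
}
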