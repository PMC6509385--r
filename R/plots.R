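#' Plot a skin-temperature trace with its torpor threshold
#'
#' Skin temperature over time for one or more individuals, with the
#' per-individual onset threshold as a dashed line and detected sub-threshold
#' readings emphasized. Ambient temperature is underlaid when supplied.
#'
#' @param telemetry Telemetry tibble.
#' @param thresholds Optional [torpor_threshold()] tibble.
#' @param ambient Optional ambient tibble (`timestamp`, `t_a`).
#' @param individuals Subset of individual ids to show (default: first one).
#' @return A ggplot.
#' @export
plot_telemetry <- function(telemetry, thresholds = NULL, ambient = NULL,
                           individuals = NULL) {
  individuals <- individuals %||% telemetry$individual_id[1]
  df <- telemetry |> filter(.data$individual_id %in% individuals)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$timestamp, y = .data$t_sk))
  if (!is.null(ambient)) {
    amb <- ambient |>
      filter(
        .data$timestamp >= min(df$timestamp),
        .data$timestamp <= max(df$timestamp)
      )
    p <- p + ggplot2::geom_line(
      data = amb, ggplot2::aes(y = .data$t_a),
      colour = "grey70", linewidth = 0.3
    )
  }
  p <- p + ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~individual_id, ncol = 1)
  if (!is.null(thresholds)) {
    thr <- thresholds |> filter(.data$individual_id %in% individuals)
    p <- p + ggplot2::geom_hline(
      data = thr, ggplot2::aes(yintercept = .data$t_onset),
      linetype = "dashed", colour = "grey40"
    )
  }
  p + ggplot2::labs(x = NULL, y = "Skin temperature (°C)") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_telemetry autoplot method for a simulation object.
#' @param object A `torpor_simulation`.
#' @param ... Passed to `plot_telemetry()`.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.torpor_simulation <- function(object, ...) {
  plot_telemetry(object$telemetry, ...)
}

#' Plot DIC weights of a model ranking
#'
#' @param object A [rank_models()] table.
#' @param ... Unused.
#' @return A ggplot: models ordered by rank with their DIC weight; the
#'   confidence-set members are filled.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.torpor_rank_table <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(model = factor(.data$model, levels = rev(.data$model)))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$weight, y = .data$model, fill = .data$in_conf_set
  )) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(
      values = c(`TRUE` = "grey30", `FALSE` = "grey80"),
      name = "95% set"
    ) +
    ggplot2::labs(x = "DIC weight", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a fitted weather effect curve
#'
#' The logistic (frequency) or linear (duration/depth) response implied by
#' model-averaged estimates, as in effect plots of torpor probability
#' against wind or precipitation.
#'
#' @param beta0,slope Averaged intercept and slope.
#' @param family `"bernoulli"` or `"normal"`.
#' @param x Covariate grid.
#' @param xlab,ylab Axis labels.
#' @return A ggplot.
#' @export
plot_effect_curve <- function(beta0, slope, family = "bernoulli",
                              x = seq(0, 50, by = 0.5),
                              xlab = "Covariate", ylab = "Response") {
  df <- effect_curve(beta0, slope, x, family)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = xlab, y = ylab) +
    ggplot2::theme_minimal()
}
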