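#' Per-individual torpor onset threshold
#'
#' The torpor onset threshold for an individual is defined as 3 deg C below
#' the 80th percentile of all of that individual's skin-temperature
#' readings. The percentile uses linear interpolation between order
#' statistics (R's default quantile type 7); the percentile, offset and
#' quantile type are configurable.
#'
#' All readings of the individual enter the percentile, whether or not they
#' fall inside retained bat days.
#'
#' @param telemetry Tibble with columns `individual_id` and `t_sk` (other
#'   columns ignored); may contain several individuals.
#' @param percentile Percentile of the skin-temperature distribution
#'   (default 0.80).
#' @param offset_c Offset subtracted from the percentile, deg C (default 3).
#' @param type Quantile algorithm passed to [stats::quantile()].
#' @param min_readings Minimum readings required per individual.
#' @return A tibble `individual_id`, `t_onset`.
#' @examples
#' tele <- tibble::tibble(individual_id = "a", t_sk = c(30, 31, 32, 33, 34))
#' torpor_threshold(tele, min_readings = 5) # 33.2 - 3 = 30.2
#' @export
torpor_threshold <- function(telemetry, percentile = 0.80, offset_c = 3,
                             type = 7, min_readings = 10) {
  if (nrow(telemetry) == 0) abort("`telemetry` has no readings.")
  out <- telemetry |>
    group_by(.data$individual_id) |>
    summarise(
      n = sum(!is.na(.data$t_sk)),
      t_onset = quantile(.data$t_sk, percentile, na.rm = TRUE, type = type,
        names = FALSE
      ) - offset_c,
      .groups = "drop"
    )
  short <- out$individual_id[out$n < min_readings]
  if (length(short)) {
    abort(sprintf(
      "Too few readings (< %d) for individual(s): %s",
      min_readings, paste(short, collapse = ", ")
    ))
  }
  out |> select("individual_id", "t_onset")
}
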