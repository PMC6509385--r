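#' Infer roost occupancy from telemetry gaps
#'
#' Receivers stationed at the roost only log a transmitter while the bat is
#' inside, so absences appear as runs of missing expected readings. A run of
#' at least `min_gap` consecutive missing readings that touches the night
#' period (default 20:00-07:00) is treated as the bat being away foraging;
#' shorter gaps and daytime gaps are treated as logging dropouts, not
#' absence.
#'
#' @param telemetry Telemetry tibble (`individual_id`, `timestamp`, `t_sk`).
#' @param cadence_min Sampling cadence, minutes.
#' @param night_hours `c(start, end)` clock hours bounding the night period
#'   (wrapping midnight).
#' @param min_gap Minimum consecutive missing readings to call an absence.
#' @return Tibble `individual_id`, `start`, `end` of presence intervals.
#' @export
infer_occupancy <- function(telemetry, cadence_min = 10,
                            night_hours = c(20, 7), min_gap = 2) {
  step_s <- cadence_min * 60
  telemetry |>
    group_by(.data$individual_id) |>
    group_modify(function(df, key) {
      ts <- sort(unique(as.double(df$timestamp)))
      grid <- seq(ts[1], ts[length(ts)], by = step_s)
      present <- grid %in% ts
      r <- rle(present)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      hour <- (grid / 3600) %% 24
      is_night <- hour >= night_hours[1] | hour < night_hours[2]
      # a missing run is an absence only if long enough and touching night
      absence <- !r$values & r$lengths >= min_gap &
        purrr::map_lgl(seq_along(r$values), function(i) {
          any(is_night[starts[i]:ends[i]])
        })
      present2 <- rep(!absence, r$lengths) # fill logging dropouts
      r2 <- rle(present2)
      e2 <- cumsum(r2$lengths)
      s2 <- e2 - r2$lengths + 1L
      keep <- which(r2$values)
      tibble(
        start = as.POSIXct(grid[s2[keep]], origin = "1970-01-01", tz = "UTC"),
        end = as.POSIXct(grid[e2[keep]], origin = "1970-01-01", tz = "UTC")
      )
    }) |>
    ungroup()
}

#' Segment telemetry into bat days
#'
#' A bat day runs from the final arrival at the roost until emergence the
#' following night; when a bat does not leave the roost overnight, the day
#' is anchored to the calendar: midnight to the last reading slot of the
#' day (23:50 at a 10-min cadence). Operationally, each presence interval is
#' split at midnight and each within-date piece becomes one bat day, so a
#' day the bat slept through entirely gets the full midnight-to-23:50
#' window, while arrival and emergence days are clipped to the actual
#' arrival/emergence times. If several presence intervals fall on one date
#' (the bat left and returned), only the piece starting at the final
#' arrival is kept.
#'
#' @param telemetry Telemetry tibble (`individual_id`, `timestamp`, `t_sk`,
#'   optionally `condition`).
#' @param occupancy Presence intervals (`individual_id`, `start`, `end`);
#'   inferred via [infer_occupancy()] when `NULL`.
#' @param cadence_min Sampling cadence, minutes.
#' @param ... Passed to [infer_occupancy()].
#' @return A tibble with one row per bat day: `individual_id`, `condition`
#'   (if present), `date`, `win_start`, `win_end`, `expected_n`,
#'   `observed_n`, `missing_min` where
#'   `missing_min = cadence * (expected - observed)`.
#' @examples
#' p <- truth_params(seed = 5, missing_rate = 0)
#' env <- generate_environment(15, p)
#' sim <- simulate_telemetry(generate_cohort(c(L = 2), p), env, p)
#' segment_bat_days(sim$telemetry, sim$occupancy)
#' @export
segment_bat_days <- function(telemetry, occupancy = NULL, cadence_min = 10, ...) {
  if (is.null(occupancy)) {
    occupancy <- infer_occupancy(telemetry, cadence_min = cadence_min, ...)
  }
  step_s <- cadence_min * 60

  tele_range <- range(as.Date(telemetry$timestamp, tz = "UTC"))
  occ_range <- range(as.Date(occupancy$start, tz = "UTC"), as.Date(occupancy$end, tz = "UTC"))
  if (occ_range[1] > tele_range[2] || occ_range[2] < tele_range[1]) {
    abort("`occupancy` and `telemetry` cover disjoint date ranges.")
  }

  conditions <- NULL
  if ("condition" %in% names(telemetry)) {
    conditions <- telemetry |> distinct(.data$individual_id, .data$condition)
  }

  windows <- occupancy |>
    mutate(.row = dplyr::row_number()) |>
    group_by(.data$.row, .data$individual_id) |>
    group_modify(function(iv, key) {
      dates <- seq(as.Date(iv$start, tz = "UTC"), as.Date(iv$end, tz = "UTC"), by = "day")
      day0 <- as.POSIXct(paste(dates, "00:00:00"), tz = "UTC")
      day_last <- day0 + (24 * 60 - cadence_min) * 60
      tibble(
        date = dates,
        win_start = pmax(iv$start, day0),
        win_end = pmin(iv$end, day_last)
      )
    }) |>
    ungroup() |>
    select(-".row") |>
    filter(.data$win_end >= .data$win_start) |>
    # final-arrival rule: keep the latest-starting window on each date
    group_by(.data$individual_id, .data$date) |>
    slice_max(.data$win_start, n = 1, with_ties = FALSE) |>
    ungroup()

  obs <- telemetry |>
    mutate(date = as.Date(.data$timestamp, tz = "UTC"))

  out <- windows |>
    mutate(
      expected_n = as.integer(
        floor(as.double(difftime(.data$win_end, .data$win_start, units = "secs")) / step_s)
      ) + 1L
    )
  counts <- purrr::pmap_int(
    list(out$individual_id, out$win_start, out$win_end),
    function(id, ws, we) {
      sum(telemetry$individual_id == id &
        telemetry$timestamp >= ws & telemetry$timestamp <= we)
    }
  )
  out <- out |>
    mutate(
      observed_n = counts,
      missing_min = cadence_min * (.data$expected_n - .data$observed_n)
    )
  if (!is.null(conditions)) {
    out <- out |>
      left_join(conditions, by = "individual_id") |>
      relocate("condition", .after = "individual_id")
  }
  arrange(out, .data$individual_id, .data$date)
}

#' Drop bat days with too much missing data
#'
#' Bat days missing more than `max_missing_min` minutes of skin-temperature
#' data are excluded from analysis (strictly greater: a day missing exactly
#' the cap is retained).
#'
#' @param bat_days Output of [segment_bat_days()].
#' @param max_missing_min Missing-data cap in minutes (default 60).
#' @param quiet Suppress the dropped-count message.
#' @return The retained rows, with attribute `n_dropped`.
#' @export
filter_incomplete <- function(bat_days, max_missing_min = 60, quiet = FALSE) {
  keep <- bat_days$missing_min <= max_missing_min
  stage_log(
    "filter_incomplete", "%d of %d bat days retained (%d dropped for >%d min missing)",
    sum(keep), length(keep), sum(!keep), max_missing_min,
    quiet = quiet
  )
  out <- bat_days[keep, ]
  attr(out, "n_dropped") <- sum(!keep)
  out
}
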