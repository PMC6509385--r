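#' Detect torpor bouts and daily torpor responses
#'
#' A bat is classified as torpid whenever skin temperature falls strictly
#' below its onset threshold for at least `min_run` consecutive readings
#' (two readings = 20 min at the 10-min cadence). Bouts are maximal runs of
#' consecutive sub-threshold readings; a missing reading breaks a run, and
#' runs are truncated at the bat-day window edges. For each bat day this
#' returns the three daily responses: `torpid` (any bout), `duration_min`
#' (10 min per sub-threshold reading inside bouts, summed over bouts) and
#' `depth_c` (the minimum skin temperature over the whole day, torpid or
#' not).
#'
#' @param telemetry Telemetry tibble.
#' @param bat_days Bat-day windows from [segment_bat_days()] (normally after
#'   [filter_incomplete()]).
#' @param thresholds Per-individual thresholds from [torpor_threshold()].
#' @param min_run Minimum consecutive sub-threshold readings per bout.
#' @param cadence_min Sampling cadence, minutes.
#' @param keep_bouts If `TRUE`, add a list-column `bouts` of per-day tibbles
#'   with bout `start`/`end` timestamps and `n_readings`.
#' @return `bat_days` with columns `torpid`, `duration_min`, `depth_c`,
#'   `n_bouts` (and optionally `bouts`) appended.
#' @export
detect_bouts <- function(telemetry, bat_days, thresholds, min_run = 2,
                         cadence_min = 10, keep_bouts = FALSE) {
  if (any(bat_days$observed_n == 0)) {
    abort("Bat day(s) with zero readings; filter or fix the windows first.")
  }
  step_s <- cadence_min * 60
  thr <- setNames(thresholds$t_onset, thresholds$individual_id)

  res <- purrr::pmap(
    list(bat_days$individual_id, bat_days$win_start, bat_days$win_end),
    function(id, ws, we) {
      rows <- telemetry$individual_id == id &
        telemetry$timestamp >= ws & telemetry$timestamp <= we
      tt <- telemetry$timestamp[rows]
      xx <- telemetry$t_sk[rows]
      o <- order(tt)
      tt <- tt[o]
      xx <- xx[o]
      pos <- as.integer(round(as.double(tt - ws, units = "secs") / step_s))
      sub <- xx < thr[[id]]
      # run ids: breaks where not sub-threshold or grid position jumps
      brk <- c(TRUE, diff(pos) != 1L | !sub[-1] | !sub[-length(sub)])
      run_id <- cumsum(brk)
      run_id[!sub] <- NA_integer_
      runs <- split(seq_along(tt)[!is.na(run_id)], run_id[!is.na(run_id)])
      runs <- runs[lengths(runs) >= min_run]
      dur <- sum(lengths(runs)) * cadence_min
      bouts <- tibble(
        start = as.POSIXct(vapply(runs, function(i) as.double(tt[i[1]]), 0),
          origin = "1970-01-01", tz = "UTC"
        ),
        end = as.POSIXct(
          vapply(runs, function(i) as.double(tt[i[length(i)]]), 0),
          origin = "1970-01-01", tz = "UTC"
        ),
        n_readings = lengths(runs) |> unname()
      )
      list(
        torpid = length(runs) > 0, duration_min = dur,
        depth_c = min(xx), n_bouts = length(runs), bouts = bouts
      )
    }
  )

  out <- bat_days |>
    mutate(
      torpid = map_lgl(res, "torpid"),
      duration_min = map_dbl(res, "duration_min"),
      depth_c = map_dbl(res, "depth_c"),
      n_bouts = purrr::map_int(res, "n_bouts")
    )
  if (keep_bouts) out$bouts <- map(res, "bouts")
  out
}

#' Torpor frequency by group
#'
#' The proportion of bat days on which the individual was torpid, by any
#' grouping of the daily table (reproductive condition, individual, date,
#' or overall). The per-day 0/1 responses consumed by the frequency models
#' are the `torpid` column of the daily table itself.
#'
#' @param daily Daily torpor table from [detect_bouts()] or
#'   [extract_torpor_metrics()].
#' @param ... Grouping columns (tidy-select, as in [dplyr::group_by()]);
#'   none = overall proportion.
#' @return Tibble with `n_days`, `n_torpid`, `frequency` per group.
#' @examples
#' daily <- tibble::tibble(condition = c("P", "P", "L", "L"),
#'                         torpid = c(TRUE, TRUE, TRUE, FALSE))
#' summarize_frequency(daily, condition)
#' @export
summarize_frequency <- function(daily, ...) {
  if (nrow(daily) == 0) abort("`daily` has no bat days.")
  daily |>
    group_by(...) |>
    summarise(
      n_days = dplyr::n(),
      n_torpid = sum(.data$torpid),
      frequency = mean(.data$torpid),
      .groups = "drop"
    )
}

#' Extract the full bat-day torpor table from telemetry
#'
#' One call from raw telemetry to the per-day analysis table: computes the
#' per-individual onset threshold (80th percentile of all readings minus
#' 3 deg C by default), segments bat days, drops days missing more than
#' `max_missing_min` minutes, and detects bouts.
#'
#' @inheritParams detect_bouts
#' @inheritParams torpor_threshold
#' @inheritParams segment_bat_days
#' @inheritParams filter_incomplete
#' @param quiet Suppress progress messages.
#' @return The daily torpor tibble: `individual_id`, `condition`, `date`,
#'   `torpid`, `duration_min`, `depth_c`, `n_bouts`, `missing_min`, window
#'   bounds.
#' @examples
#' p <- truth_params(seed = 11, missing_rate = 0)
#' env <- generate_environment(15, p)
#' sim <- simulate_telemetry(generate_cohort(c(NOP = 2), p), env, p)
#' extract_torpor_metrics(sim$telemetry, sim$occupancy, quiet = TRUE)
#' @export
extract_torpor_metrics <- function(telemetry, occupancy = NULL,
                                   percentile = 0.80, offset_c = 3,
                                   min_run = 2, max_missing_min = 60,
                                   cadence_min = 10, quiet = FALSE) {
  thresholds <- torpor_threshold(telemetry, percentile, offset_c)
  days <- segment_bat_days(telemetry, occupancy, cadence_min = cadence_min)
  days <- filter_incomplete(days, max_missing_min, quiet = quiet)
  days <- days[days$observed_n > 0, ]
  detect_bouts(telemetry, days, thresholds,
    min_run = min_run, cadence_min = cadence_min
  )
}

#' Write / read the bat-day table CSV
#'
#' Persists the daily torpor table in the schema consumed by the modeling
#' stage: individual, condition, date, torpid, duration_min, depth_c,
#' missing_min.
#'
#' @param daily Daily torpor table.
#' @param path CSV path.
#' @return `path` (writer) or a tibble (reader).
#' @export
write_bat_days_csv <- function(daily, path) {
  daily |>
    select(dplyr::any_of(c(
      "individual_id", "condition", "date", "torpid", "duration_min",
      "depth_c", "n_bouts", "missing_min"
    ))) |>
    readr::write_csv(path)
  invisible(path)
}

#' @rdname write_bat_days_csv
#' @export
read_bat_days_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    individual_id = readr::col_character(),
    condition = readr::col_character(),
    date = readr::col_date(),
    torpid = readr::col_logical(),
    duration_min = readr::col_double(),
    depth_c = readr::col_double()
  ))
}
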