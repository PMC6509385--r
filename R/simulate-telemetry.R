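#' Simulate skin-temperature telemetry for a cohort
#'
#' The generative inverse of the extraction rules: for each tracked
#' individual-day, torpor occurs with probability
#' `ilogit(beta0_logit + gamma_wind * wind + gamma_precip * precip)`; torpid
#' days get one bout of Normal-distributed length placed in the post-arrival
#' roosting period, during which skin temperature decays toward the ambient
#' trace by Newtonian cooling (floored at ambient + 1 deg C, since external
#' transmitters on torpid bats read slightly above air) and rewarms on exit;
#' all other in-roost readings sit near the normothermic mean. Bats leave
#' the roost at night to forage (readings absent while away, skin
#' temperature reset to normothermic on return) unless they stay in
#' (probability `p_stay_in`). Optionally, a fraction `missing_rate` of
#' in-roost readings is dropped at random.
#'
#' All randomness derives from `params$seed`: identical inputs give
#' byte-identical output tables.
#'
#' @param cohort A [generate_cohort()] tibble.
#' @param env An environment list from [generate_environment()].
#' @param params The same [truth_params()] used for the cohort.
#' @return A list of class `"torpor_simulation"`:
#'   * `telemetry`: tibble `individual_id`, `condition`, `timestamp`, `t_sk`;
#'   * `truth_days`: per individual-day ground truth (`torpid_true`,
#'     `bout_min` placed bout length, `target_depth`);
#'   * `occupancy`: presence intervals (`individual_id`, `start`, `end`).
#' @examples
#' p <- truth_params(seed = 3)
#' env <- generate_environment(20, p)
#' cohort <- generate_cohort(c(P = 2, L = 2), p)
#' sim <- simulate_telemetry(cohort, env, p)
#' head(sim$telemetry)
#' @export
simulate_telemetry <- function(cohort, env, params = attr(cohort, "params")) {
  if (is.null(params)) abort("`params` is required.")
  weather <- env$weather
  ambient <- env$ambient
  step_s <- params$cadence_min * 60
  t0 <- ambient$timestamp[1]
  season_dates <- weather$date

  need_last <- max(cohort$start_day + cohort$n_days - 1L)
  if (need_last > length(season_dates)) {
    abort("Cohort tracking windows extend past the simulated environment.")
  }

  ta_at <- function(times) {
    idx <- as.integer(round((as.double(times) - as.double(t0)) / step_s)) + 1L
    ambient$t_a[pmin(pmax(idx, 1L), nrow(ambient))]
  }
  on_grid <- function(date, hour) {
    snap_to_grid(as.POSIXct(paste(date, "00:00:00"), tz = "UTC") + hour * 3600,
      params$cadence_min
    )
  }

  withr::with_seed(child_seed(params$seed, 303L), {
    tele <- vector("list", nrow(cohort))
    truth <- vector("list", nrow(cohort))
    occ <- vector("list", nrow(cohort))

    for (i in seq_len(nrow(cohort))) {
      ind <- cohort[i, ]
      dates <- season_dates[seq(ind$start_day, ind$start_day + ind$n_days - 1L)]
      k <- length(dates)
      wx <- weather[match(dates, weather$date), ]

      arrivals <- on_grid(dates, pmin(pmax(rnorm(k, params$arrival_hour, 0.5), 0.5), 8))
      emergences <- on_grid(dates, pmin(pmax(rnorm(k, params$emergence_hour, 0.5), 19), 23.5))
      stay_in <- rbinom(k, 1, params$p_stay_in) == 1 # night after day d

      eta <- params$beta0_logit + params$gamma_wind * wx$max_wind_kmh +
        params$gamma_precip * wx$precip_mm
      torpid <- rbinom(k, 1, ilogit(eta)) == 1

      # presence intervals: arrival of a run of days .. emergence ending it
      pres_start <- arrivals[1]
      intervals <- list()
      for (d in seq_len(k)) {
        leaves_tonight <- d == k || !stay_in[d]
        if (leaves_tonight) {
          intervals[[length(intervals) + 1L]] <- c(pres_start, emergences[d])
          if (d < k) pres_start <- arrivals[d + 1L]
        }
      }

      # per-day bout placement
      bout_start <- rep(as.POSIXct(NA), k)
      bout_steps <- integer(k)
      target_depth <- rnorm(
        k, params$base_depth + ind$depth_effect,
        params$sigma_day[["depth"]]
      )
      for (d in seq_len(k)) {
        if (!torpid[d]) next
        win_start <- if (d == 1 || !stay_in[d - 1]) {
          arrivals[d]
        } else {
          on_grid(dates[d], 0)
        }
        lo <- win_start + 3L * step_s
        hi <- emergences[d] - 2L * step_s
        cap <- as.integer(floor(as.double(difftime(hi, lo, units = "secs")) / step_s))
        if (cap < 2L) {
          torpid[d] <- FALSE
          next
        }
        want <- rnorm(
          1, params$base_duration + ind$dur_effect,
          params$sigma_day[["duration"]]
        )
        steps <- max(2L, as.integer(round(want / params$cadence_min)))
        steps <- min(steps, cap)
        slack <- cap - steps
        offset <- if (slack > 0) sample(0:slack, 1L) else 0L
        bout_start[d] <- lo + offset * step_s
        bout_steps[d] <- steps
      }
      bout_end <- bout_start + bout_steps * step_s # exclusive

      # walk the presence grid
      series <- vector("list", length(intervals))
      for (j in seq_along(intervals)) {
        iv <- intervals[[j]]
        times <- seq(iv[1], iv[2], by = step_s)
        ta <- ta_at(times)
        tsk <- numeric(length(times))
        temp <- params$t_normothermic
        day_idx <- match(as.Date(times, tz = "UTC"), dates)
        in_bout <- !is.na(day_idx) & torpid[pmin(pmax(day_idx, 1L), k)] &
          !is.na(bout_start[pmin(pmax(day_idx, 1L), k)]) &
          times >= bout_start[pmin(pmax(day_idx, 1L), k)] &
          times < bout_end[pmin(pmax(day_idx, 1L), k)]
        for (s in seq_along(times)) {
          if (isTRUE(in_bout[s])) {
            fl <- max(target_depth[day_idx[s]], ta[s] + 1)
            fl <- min(fl, params$t_normothermic)
            temp <- temp + params$cooling_rate * (fl - temp)
            tsk[s] <- temp + rnorm(1, 0, 0.1)
          } else if (temp < params$t_normothermic - 0.5) {
            temp <- temp + params$rewarm_rate * (params$t_normothermic - temp)
            tsk[s] <- temp + rnorm(1, 0, 0.1)
          } else {
            temp <- params$t_normothermic
            tsk[s] <- rnorm(1, params$t_normothermic, params$normo_sd)
          }
        }
        series[[j]] <- tibble(timestamp = times, t_sk = tsk)
      }
      trace <- list_rbind(series)
      if (params$missing_rate > 0) {
        keep <- runif(nrow(trace)) >= params$missing_rate
        trace <- trace[keep, ]
      }

      tele[[i]] <- trace |>
        mutate(
          individual_id = ind$individual_id, condition = ind$condition,
          .before = 1
        )
      truth[[i]] <- tibble(
        individual_id = ind$individual_id, condition = ind$condition,
        date = dates, torpid_true = torpid,
        bout_start = bout_start,
        bout_min = bout_steps * params$cadence_min,
        target_depth = ifelse(torpid, target_depth, NA_real_)
      )
      occ[[i]] <- tibble(
        individual_id = ind$individual_id,
        start = as.POSIXct(vapply(intervals, function(x) as.double(x[1]), 0),
          origin = "1970-01-01", tz = "UTC"
        ),
        end = as.POSIXct(vapply(intervals, function(x) as.double(x[2]), 0),
          origin = "1970-01-01", tz = "UTC"
        )
      )
    }

    structure(
      list(
        telemetry = list_rbind(tele),
        truth_days = list_rbind(truth),
        occupancy = list_rbind(occ)
      ),
      class = "torpor_simulation", params = params
    )
  })
}

#' @export
print.torpor_simulation <- function(x, ...) {
  cat("<torpor_simulation>\n")
  cat(sprintf(
    "  %d individuals, %d bat days (%d torpid), %d readings\n",
    dplyr::n_distinct(x$truth_days$individual_id),
    nrow(x$truth_days), sum(x$truth_days$torpid_true), nrow(x$telemetry)
  ))
  invisible(x)
}

#' Write a simulated data set to CSV (+ truth JSON)
#'
#' Writes `telemetry.csv` (individual_id, condition, timestamp ISO-8601,
#' t_sk), `ambient.csv` (timestamp, t_a), `weather.csv` (date, max_wind_kmh,
#' precip_mm, min_ta) and `truth.json` (generator parameters and
#' per-individual effects) into `dir`.
#'
#' @param sim A [simulate_telemetry()] result.
#' @param env The matching [generate_environment()] result.
#' @param cohort The matching [generate_cohort()] tibble.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation_csv <- function(sim, env, cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  params <- attr(sim, "params")
  tele <- sim$telemetry |>
    mutate(timestamp = format(.data$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
  readr::write_csv(tele, file.path(dir, "telemetry.csv"))
  amb <- env$ambient |>
    mutate(timestamp = format(.data$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
  readr::write_csv(amb, file.path(dir, "ambient.csv"))
  readr::write_csv(env$weather, file.path(dir, "weather.csv"))
  truth <- list(
    params = unclass(params)[setdiff(names(params), "condition_effects")],
    condition_effects = params$condition_effects,
    individuals = as.data.frame(cohort)
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}

#' Read telemetry / ambient / weather CSVs
#'
#' Readers for the CSV layout written by [write_simulation_csv()] (or
#' hand-prepared real data in the same schema). Timestamps are parsed as UTC.
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_telemetry_csv <- function(path) {
  readr::read_csv(path,
    col_types = readr::cols(
      individual_id = readr::col_character(),
      condition = readr::col_character(),
      timestamp = readr::col_datetime(),
      t_sk = readr::col_double()
    )
  )
}

#' @rdname read_telemetry_csv
#' @export
read_ambient_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    timestamp = readr::col_datetime(), t_a = readr::col_double()
  ))
}

#' @rdname read_telemetry_csv
#' @export
read_weather_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    date = readr::col_date(), max_wind_kmh = readr::col_double(),
    precip_mm = readr::col_double(), min_ta = readr::col_double()
  ))
}
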