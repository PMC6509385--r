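#' Simulate ambient temperature and daily weather
#'
#' Generates a 10-minute ambient temperature series (diurnal sinusoid with
#' AR(1) noise, warmest mid-afternoon) and a daily weather table: maximum
#' wind speed (gamma-distributed, right-skewed), total precipitation
#' (zero-inflated gamma), and the daily minimum of the generated ambient
#' series.
#'
#' @param n_days Number of days to simulate (>= 1).
#' @param params A [truth_params()] object.
#' @param start_date First calendar date of the series.
#' @return A list with two tibbles:
#'   * `ambient`: columns `timestamp` (POSIXct, UTC, on the cadence grid),
#'     `t_a` (deg C);
#'   * `weather`: columns `date`, `max_wind_kmh`, `precip_mm`, `min_ta`.
#' @examples
#' env <- generate_environment(5, truth_params(seed = 1))
#' head(env$weather)
#' @export
generate_environment <- function(n_days, params = truth_params(),
                                 start_date = as.Date("2017-06-01")) {
  if (!is.numeric(n_days) || length(n_days) != 1L || n_days < 1) {
    abort("`n_days` must be a positive number of days.")
  }
  n_days <- as.integer(n_days)
  per_day <- as.integer(24 * 60 / params$cadence_min)
  n <- n_days * per_day

  withr::with_seed(child_seed(params$seed, 101L), {
    t0 <- as.POSIXct(paste(start_date, "00:00:00"), tz = "UTC")
    timestamp <- t0 + (seq_len(n) - 1L) * params$cadence_min * 60
    hour <- ((as.double(timestamp) - as.double(t0)) / 3600) %% 24
    # diurnal cycle peaking at 15:00
    cycle <- params$ta_amplitude * cos(2 * pi * (hour - 15) / 24)
    noise <- numeric(n)
    if (params$ta_noise_sd > 0) {
      innov_sd <- params$ta_noise_sd * sqrt(1 - params$ta_ar^2)
      noise[1] <- rnorm(1, 0, params$ta_noise_sd)
      e <- rnorm(n - 1, 0, innov_sd)
      for (i in seq_len(n - 1L)) {
        noise[i + 1L] <- params$ta_ar * noise[i] + e[i]
      }
    }
    t_a <- params$ta_mean + cycle + noise

    date <- as.Date(rep(seq(start_date, by = "day", length.out = n_days),
      each = per_day
    ))
    wind <- rgamma(n_days,
      shape = params$wind_shape,
      rate = params$wind_shape / params$wind_mean
    )
    wet <- rbinom(n_days, 1, 1 - params$precip_zero_prob)
    amount <- rgamma(n_days, shape = 1.2, rate = 1.2 / params$precip_wet_mean)
    precip <- wet * amount

    days <- seq(start_date, by = "day", length.out = n_days)
    min_ta <- as.vector(tapply(t_a, date, min)[as.character(days)])
    ambient <- tibble(timestamp = timestamp, t_a = t_a)
    weather <- tibble(
      date = days,
      max_wind_kmh = wind,
      precip_mm = precip,
      min_ta = min_ta
    )
    list(ambient = ambient, weather = weather)
  })
}
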