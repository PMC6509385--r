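#' Ground-truth parameters for the synthetic telemetry generator
#'
#' Bundles every generative parameter used by [generate_environment()],
#' [generate_cohort()] and [simulate_telemetry()], so that a simulated data
#' set carries a complete, reproducible description of how it was made.
#' Defaults emulate a summer telemetry study of female little brown bats in
#' a cool maritime climate: a cohort of ~35 females across five reproductive
#' conditions tracked for a few days each (~150 bat days), daily torpor
#' driven by weather on the log-odds scale, and bout duration/depth driven
#' by reproductive condition plus individual effects.
#'
#' The hierarchy mirrors the analysis models: each reproductive condition
#' has a mean duration/depth offset; individuals draw their own offsets
#' around their condition's mean with SD `sigma_individual`; days draw
#' around the individual with SD `sigma_day`.
#'
#' @param beta0_logit Log-odds intercept for daily torpor use (at zero wind
#'   and precipitation).
#' @param gamma_wind Log-odds change per km/hr of daily maximum wind speed.
#' @param gamma_precip Log-odds change per mm of daily total precipitation.
#' @param condition_effects Data frame with columns `condition`
#'   (exactly the five labels P, L, PL, NR, NOP), `dur_offset` (min/day
#'   relative to `base_duration`) and `depth_offset` (degrees C relative to
#'   `base_depth`).
#' @param base_duration Mean placed bout length (min/day) on torpid days,
#'   across conditions.
#' @param base_depth Mean daily minimum skin temperature (deg C) targeted on
#'   torpid days, across conditions.
#' @param sigma_individual Named vector `c(duration = , depth = )`: SD of
#'   individual effects within a condition.
#' @param sigma_day Named vector `c(duration = , depth = )`: day-level SD.
#' @param t_normothermic Mean normothermic skin temperature (deg C).
#' @param normo_sd Measurement/physiological noise around normothermy (deg C).
#' @param cooling_rate Newtonian cooling constant per 10-min step, in
#'   `[0, 1]`: each step moves skin temperature this fraction of the way to
#'   the torpid floor.
#' @param rewarm_rate Rewarming constant per 10-min step on bout exit.
#' @param ta_mean,ta_amplitude Mean and diurnal amplitude of ambient
#'   temperature (deg C).
#' @param ta_noise_sd,ta_ar SD and lag-1 autocorrelation of the AR(1) noise
#'   added to the ambient sinusoid.
#' @param wind_mean Mean of the (gamma-distributed, right-skewed) daily
#'   maximum wind speed, km/hr.
#' @param wind_shape Gamma shape for wind (smaller = more skewed).
#' @param precip_zero_prob Probability of a dry day (zero precipitation).
#' @param precip_wet_mean Mean precipitation (mm) on wet days.
#' @param missing_rate Probability that an in-roost reading is dropped
#'   (transmitter/receiver failure); set 0 to disable.
#' @param p_stay_in Probability a bat skips nightly emergence and roosts
#'   through the night.
#' @param emergence_hour,arrival_hour Mean clock hours of nightly emergence
#'   and of final return to the roost.
#' @param cadence_min Sampling cadence in minutes (the study design is 10).
#' @param season_days Length of the simulated season in days.
#' @param days_range Integer range (`c(lo, hi)`) of tracked days per
#'   individual.
#' @param seed Integer master seed; every generator call derives its stream
#'   from it, so identical parameters give byte-identical tables.
#' @return A list of class `"truth_params"`.
#' @examples
#' p <- truth_params(seed = 42)
#' p$gamma_precip
#' @export
truth_params <- function(beta0_logit = 1.1,
                         gamma_wind = 0.03,
                         gamma_precip = 0.31,
                         condition_effects = default_condition_effects(),
                         base_duration = 377.5,
                         base_depth = 25.4,
                         sigma_individual = c(duration = 100, depth = 2.5),
                         sigma_day = c(duration = 150, depth = 3),
                         t_normothermic = 35,
                         normo_sd = 0.5,
                         cooling_rate = 0.35,
                         rewarm_rate = 0.7,
                         ta_mean = 14,
                         ta_amplitude = 4,
                         ta_noise_sd = 1.5,
                         ta_ar = 0.6,
                         wind_mean = 20,
                         wind_shape = 4,
                         precip_zero_prob = 0.5,
                         precip_wet_mean = 7,
                         missing_rate = 0.02,
                         p_stay_in = 0.05,
                         emergence_hour = 21.5,
                         arrival_hour = 4,
                         cadence_min = 10,
                         season_days = 60,
                         days_range = c(3L, 6L),
                         seed = 1L) {
  condition_effects <- as_tibble(condition_effects)
  required <- c("condition", "dur_offset", "depth_offset")
  if (!all(required %in% names(condition_effects))) {
    abort("`condition_effects` needs columns condition, dur_offset, depth_offset.")
  }
  if (!setequal(condition_effects$condition, condition_labels()) ||
    nrow(condition_effects) != 5L) {
    abort("`condition_effects` must have exactly the five labels P, L, PL, NR, NOP.")
  }
  for (nm in c("sigma_individual", "sigma_day")) {
    v <- get(nm)
    if (!all(c("duration", "depth") %in% names(v)) || any(v < 0)) {
      abort(sprintf("`%s` must be c(duration = , depth = ) with nonnegative values.", nm))
    }
  }
  check_number(cooling_rate, "cooling_rate", 0, 1)
  check_number(rewarm_rate, "rewarm_rate", 0, 1)
  check_number(missing_rate, "missing_rate", 0, 1)
  check_number(precip_zero_prob, "precip_zero_prob", 0, 1)
  check_number(p_stay_in, "p_stay_in", 0, 1)
  check_number(seed, "seed")

  structure(
    list(
      beta0_logit = beta0_logit, gamma_wind = gamma_wind,
      gamma_precip = gamma_precip,
      condition_effects = condition_effects,
      base_duration = base_duration, base_depth = base_depth,
      sigma_individual = sigma_individual, sigma_day = sigma_day,
      t_normothermic = t_normothermic, normo_sd = normo_sd,
      cooling_rate = cooling_rate, rewarm_rate = rewarm_rate,
      ta_mean = ta_mean, ta_amplitude = ta_amplitude,
      ta_noise_sd = ta_noise_sd, ta_ar = ta_ar,
      wind_mean = wind_mean, wind_shape = wind_shape,
      precip_zero_prob = precip_zero_prob, precip_wet_mean = precip_wet_mean,
      missing_rate = missing_rate, p_stay_in = p_stay_in,
      emergence_hour = emergence_hour, arrival_hour = arrival_hour,
      cadence_min = cadence_min, season_days = season_days,
      days_range = as.integer(days_range), seed = as.integer(seed)
    ),
    class = "truth_params"
  )
}

#' The five reproductive-condition labels
#'
#' P pregnant, L lactating, PL post-lactating, NR nonreproductive,
#' NOP not-obviously-pregnant (early spring).
#' @return Character vector of length 5.
#' @export
condition_labels <- function() c("P", "L", "PL", "NR", "NOP")

#' Default condition effects on bout duration and depth
#'
#' Offsets (min/day and deg C of daily minimum skin temperature) of each
#' reproductive condition relative to the across-condition means, matching
#' the pattern reported for little brown bats: early-spring females torpid
#' longest and deepest, lactating females shortest and shallowest.
#' @return A tibble with columns condition, dur_offset, depth_offset.
#' @export
default_condition_effects <- function() {
  tibble(
    condition = c("P", "L", "PL", "NR", "NOP"),
    dur_offset = c(-36.5, -155.8, -50.9, -71.6, 314.7),
    depth_offset = c(-0.4, 4.7, -1.3, 2.2, -5.2)
  )
}

#' @export
print.truth_params <- function(x, ...) {
  cat("<truth_params>\n")
  cat(sprintf(
    "  torpor log-odds: %.2f + %.3f*wind + %.3f*precip\n",
    x$beta0_logit, x$gamma_wind, x$gamma_precip
  ))
  cat(sprintf(
    "  duration %.0f min/day, depth %.1f degC (base), normothermic %.1f degC\n",
    x$base_duration, x$base_depth, x$t_normothermic
  ))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}
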