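# Independent brute-force oracles used across test files.

# Run-length scanner over a logical sub-threshold sequence with grid
# positions: walks the sequence element by element, opening a run when the
# current reading is sub-threshold and adjacent to the previous one, and
# closing it otherwise. Returns total readings in qualifying runs and the
# per-run lengths.
bf_bout_scan <- function(sub, pos = seq_along(sub), min_run = 2) {
  runs <- integer(0)
  cur <- 0L
  last_pos <- NA_integer_
  for (i in seq_along(sub)) {
    if (sub[i]) {
      if (cur > 0L && pos[i] == last_pos + 1L) {
        cur <- cur + 1L
      } else {
        if (cur >= min_run) runs <- c(runs, cur)
        cur <- 1L
      }
      last_pos <- pos[i]
    } else {
      if (cur >= min_run) runs <- c(runs, cur)
      cur <- 0L
      last_pos <- pos[i]
    }
  }
  if (cur >= min_run) runs <- c(runs, cur)
  list(n_bouts = length(runs), total = sum(runs))
}

# Exhaustive HDI: try every pair of order statistics that covers at least
# ceiling(mass * n) samples and keep the narrowest.
bf_hdi <- function(x, mass = 0.95) {
  s <- sort(x)
  n <- length(s)
  m <- ceiling(mass * n)
  best <- c(-Inf, Inf)
  for (i in seq_len(n)) {
    j <- i + m - 1L
    if (j > n) break
    if (s[j] - s[i] < best[2] - best[1]) best <- c(s[i], s[j])
  }
  best
}

# Sort-and-interpolate percentile (linear between order statistics)
bf_pctl <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Telemetry for one individual from a vector of skin temperatures on a
# continuous 10-min grid starting at midnight UTC.
make_trace <- function(t_sk, id = "b1", condition = "P",
                       start = as.POSIXct("2017-06-01 00:00:00", tz = "UTC"),
                       drop = integer(0)) {
  out <- tibble::tibble(
    individual_id = id, condition = condition,
    timestamp = start + (seq_along(t_sk) - 1L) * 600,
    t_sk = t_sk
  )
  if (length(drop)) out <- out[-drop, ]
  out
}

# One midnight-to-23:50 bat-day window over a full-day trace
full_day_window <- function(telemetry) {
  segment_bat_days(
    telemetry,
    occupancy = tibble::tibble(
      individual_id = telemetry$individual_id[1],
      start = min(telemetry$timestamp),
      end = max(telemetry$timestamp)
    )
  )
}

# Small synthetic study used by several files (seeded, no missing data)
make_small_study <- function(seed = 5, n_per_condition = c(P = 4, L = 4, NOP = 3),
                             season_days = 30, ...) {
  p <- truth_params(seed = seed, missing_rate = 0, season_days = season_days, ...)
  env <- generate_environment(season_days, p)
  cohort <- generate_cohort(n_per_condition, p)
  sim <- simulate_telemetry(cohort, env, p)
  daily <- extract_torpor_metrics(sim$telemetry, sim$occupancy, quiet = TRUE)
  list(p = p, env = env, cohort = cohort, sim = sim, daily = daily)
}
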