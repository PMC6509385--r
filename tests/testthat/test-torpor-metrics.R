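test_that("threshold is the interpolated 80th percentile minus 3", {
  expect_equal(
    torpor_threshold(make_trace(rep(35, 12)))$t_onset, 32
  )
  expect_equal(
    torpor_threshold(make_trace(c(30, 31, 32, 33, 34)), min_readings = 5)$t_onset,
    30.2
  )
  expect_error(torpor_threshold(make_trace(numeric(0))), "no readings")
  expect_error(torpor_threshold(make_trace(rep(35, 5))), "Too few")

  set.seed(71)
  for (i in 1:20) {
    x <- rnorm(sample(10:200, 1), mean = 30, sd = runif(1, 0.5, 6))
    got <- torpor_threshold(make_trace(x))$t_onset
    expect_equal(got, bf_pctl(x, 0.8) - 3) # sort-and-interpolate oracle
    expect_lt(got, max(x)) # always below the series maximum
    shift <- runif(1, -5, 5)
    expect_equal(
      torpor_threshold(make_trace(x + shift))$t_onset, got + shift
    ) # translation equivariance
  }
})

test_that("continuous multi-day traces segment into midnight-anchored bat days", {
  tele <- make_trace(rnorm(288, 35, 0.5)) # 48 h, no absences
  days <- full_day_window(tele)
  expect_equal(nrow(days), 2)
  expect_equal(format(days$win_start, "%H:%M"), c("00:00", "00:00"))
  expect_equal(format(days$win_end, "%H:%M"), c("23:50", "23:50"))
  expect_equal(days$expected_n, c(144, 144))
  expect_equal(days$missing_min, c(0, 0))
})

test_that("arrival-to-emergence days keep their own window", {
  start <- as.POSIXct("2017-06-01 04:00:00", tz = "UTC")
  n <- as.integer((21.5 - 4) * 6) + 1L # 04:00 .. 21:30
  tele <- make_trace(rnorm(n, 35, 0.5), start = start)
  days <- segment_bat_days(
    tele,
    occupancy = tibble::tibble(
      individual_id = "b1",
      start = start, end = start + (n - 1L) * 600
    )
  )
  expect_equal(nrow(days), 1)
  expect_equal(format(days$win_start, "%H:%M"), "04:00")
  expect_equal(format(days$win_end, "%H:%M"), "21:30")
  expect_equal(days$missing_min, 0)
})

test_that("bat-day windows partition occupied time (oracle equivalence)", {
  set.seed(81)
  day0 <- as.POSIXct("2017-06-01 00:00:00", tz = "UTC")
  for (rep in 1:10) {
    # random occupancy: one presence interval per night-to-night cycle,
    # arrival 00:00-08:00, emergence 19:00-23:50, possibly spanning days
    n_iv <- sample(2:4, 1)
    starts <- ends <- as.POSIXct(character(0), tz = "UTC")
    cursor <- day0
    for (k in seq_len(n_iv)) {
      a <- cursor + sample(0:48, 1) * 600
      e <- a + sample(36:400, 1) * 600
      starts <- c(starts, a)
      ends <- c(ends, e)
      cursor <- as.POSIXct(
        paste(as.Date(e, tz = "UTC") + 1, "00:00:00"),
        tz = "UTC"
      )
    }
    occ <- tibble::tibble(individual_id = "b1", start = starts, end = ends)
    grid <- do.call(c, purrr::map2(starts, ends, ~ seq(.x, .y, by = 600)))
    tele <- tibble::tibble(
      individual_id = "b1", timestamp = grid, t_sk = rnorm(length(grid), 35, 0.5)
    )
    days <- segment_bat_days(tele, occ)
    # oracle: each occupied grid slot must fall in exactly one window
    hits <- purrr::map_int(
      seq_along(grid),
      function(i) sum(grid[i] >= days$win_start & grid[i] <= days$win_end)
    )
    expect_true(all(hits == 1L))
    # and windows never overlap
    o <- order(days$win_start)
    expect_true(all(diff(as.double(days$win_start[o])) > 0))
    expect_true(all(
      as.double(days$win_end[o][-nrow(days)]) < as.double(days$win_start[o][-1])
    ))
  }
})

test_that("incomplete-day filter drops strictly above the 60-min cap", {
  tele <- make_trace(rnorm(288, 35, 0.5))
  days <- full_day_window(tele)
  days$missing_min <- c(60, 70)
  kept <- filter_incomplete(days, quiet = TRUE)
  expect_equal(kept$missing_min, 60)
  expect_equal(attr(kept, "n_dropped"), 1L)

  days$missing_min <- c(0, 0)
  expect_equal(nrow(filter_incomplete(days, quiet = TRUE)), nrow(days))
})

test_that("bout detection matches the run-length oracle on random sequences", {
  thr <- tibble::tibble(individual_id = "b1", t_onset = 30)
  set.seed(91)
  for (rep in 1:200) {
    n <- sample(10:48, 1)
    sub <- runif(n) < runif(1, 0.2, 0.8)
    drop <- if (runif(1) < 0.4) sample(2:(n - 1), sample(1:3, 1)) else integer(0)
    tele <- make_trace(ifelse(sub, 25, 35), drop = drop)
    keep_mask <- !(seq_len(n) %in% drop)
    days <- tibble::tibble(
      individual_id = "b1", date = as.Date("2017-06-01"),
      win_start = as.POSIXct("2017-06-01 00:00:00", tz = "UTC"),
      win_end = as.POSIXct("2017-06-01 00:00:00", tz = "UTC") + (n - 1) * 600,
      expected_n = n, observed_n = sum(keep_mask),
      missing_min = 10 * (n - sum(keep_mask))
    )
    got <- detect_bouts(tele, days, thr)
    oracle <- bf_bout_scan(sub[keep_mask], pos = which(keep_mask))
    expect_equal(got$n_bouts, oracle$n_bouts)
    expect_equal(got$duration_min, 10 * oracle$total)
    expect_equal(got$torpid, oracle$n_bouts > 0)
    expect_equal(got$depth_c, min(tele$t_sk))
  }
})

test_that("single isolated sub-threshold readings never count as torpor", {
  thr <- tibble::tibble(individual_id = "b1", t_onset = 30)
  x <- rep(35, 144)
  x[50] <- 20
  tele <- make_trace(x)
  got <- detect_bouts(tele, full_day_window(tele), thr)
  expect_false(got$torpid)
  expect_equal(got$duration_min, 0)
  expect_equal(got$depth_c, 20) # depth is the day minimum regardless

  # ties at the threshold are not torpid (strict inequality)
  x2 <- rep(30, 144)
  got2 <- detect_bouts(make_trace(x2), full_day_window(make_trace(x2)), thr)
  expect_false(got2$torpid)

  # a fully sub-threshold midnight-anchored day is one 1440-min bout
  x3 <- rep(25, 144)
  got3 <- detect_bouts(make_trace(x3), full_day_window(make_trace(x3)), thr)
  expect_true(got3$torpid)
  expect_equal(got3$duration_min, 1440)
  expect_equal(got3$n_bouts, 1)
})

test_that("removing readings splits runs and never increases duration", {
  thr <- tibble::tibble(individual_id = "b1", t_onset = 30)
  set.seed(101)
  for (rep in 1:30) {
    n <- 60
    sub <- runif(n) < 0.6
    tele <- make_trace(ifelse(sub, 25, 35))
    base <- detect_bouts(tele, full_day_window(tele), thr)
    drop <- sample(2:(n - 1), sample(1:6, 1))
    tele2 <- make_trace(ifelse(sub, 25, 35), drop = drop)
    days2 <- full_day_window(tele2)
    days2$observed_n <- n - length(drop)
    got <- detect_bouts(tele2, days2, thr)
    expect_lte(got$duration_min, base$duration_min)
  }

  # a gap inserted inside a long run splits it in two
  x <- rep(25, 20)
  tele_gap <- make_trace(c(rep(35, 5), x, rep(35, 5)), drop = 15)
  days <- full_day_window(tele_gap)
  got <- detect_bouts(tele_gap, days, thr)
  expect_equal(got$n_bouts, 2)
  expect_equal(got$duration_min, 190)
})

test_that("frequency summaries are plain proportions by group", {
  daily <- tibble::tibble(
    condition = c("P", "P", "P", "P", "L", "L"),
    torpid = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE)
  )
  out <- summarize_frequency(daily, condition)
  expect_equal(out$frequency[out$condition == "P"], 0.75)
  expect_equal(out$frequency[out$condition == "L"], 1.0)
  expect_equal(summarize_frequency(daily)$frequency, mean(daily$torpid))
  expect_equal(
    summarize_frequency(tibble::tibble(torpid = c(FALSE, FALSE)))$frequency, 0
  )
  expect_error(summarize_frequency(daily[0, ]), "no bat days")
})

test_that("extracted durations recover generated bout lengths end to end", {
  eff <- default_condition_effects()
  eff$depth_offset <- rep(-6, 5)
  p <- truth_params(
    seed = 111, missing_rate = 0, condition_effects = eff,
    sigma_day = c(duration = 120, depth = 1),
    sigma_individual = c(duration = 80, depth = 1),
    season_days = 30
  )
  env <- generate_environment(30, p)
  sim <- simulate_telemetry(generate_cohort(c(P = 6, NOP = 5), p), env, p)
  daily <- extract_torpor_metrics(sim$telemetry, sim$occupancy, quiet = TRUE)
  joined <- merge(daily, sim$truth_days, by = c("individual_id", "date"))
  expect_gte(nrow(joined), 40)
  within20 <- abs(joined$duration_min - joined$bout_min) <= 20
  expect_gte(mean(within20), 0.95)
})
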