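# minimal bat-day table + weather for design-data tests
toy_tables <- function(n = 12, seed = 1) {
  set.seed(seed)
  dates <- as.Date("2017-06-01") + seq_len(n) - 1
  daily <- tibble::tibble(
    individual_id = rep(c("P01", "P02", "L01"), length.out = n),
    condition = rep(c("P", "P", "L"), length.out = n),
    date = dates,
    torpid = runif(n) < 0.6,
    duration_min = round(pmax(0, rnorm(n, 300, 150)) / 10) * 10,
    depth_c = rnorm(n, 26, 4)
  )
  weather <- tibble::tibble(
    date = dates,
    max_wind_kmh = c(10, 20, 30)[rep(1:3, length.out = n)],
    precip_mm = rgamma(n, 1, 0.3),
    min_ta = rnorm(n, 10, 2)
  )
  list(daily = daily, weather = weather)
}

test_that("the candidate set is the fixed 14-model family", {
  for (resp in c("frequency", "duration", "depth")) {
    cands <- candidate_models(resp)
    expect_equal(nrow(cands), 14)
    expect_equal(anyDuplicated(purrr::map_chr(
      cands$spec, ~ paste(sort(.x$variables), collapse = "+")
    )), 0L)
    expect_true("Reproductive + Individual + Wind" %in% cands$model)
    expect_true(all(c("Precipitation + Wind", "Min Ta", "Individual") %in% cands$model))
    expect_equal(
      cands$family,
      rep(if (resp == "frequency") "bernoulli" else "normal", 14)
    )
    expect_equal(
      cands$hierarchical,
      purrr::map_lgl(cands$spec, ~ any(c("reproductive", "individual") %in% .x$variables))
    )
  }
  # variable sets are identical across the three responses
  sets <- purrr::map(c("frequency", "duration", "depth"), function(r) {
    sort(purrr::map_chr(
      candidate_models(r)$spec, ~ paste(sort(.x$variables), collapse = "+")
    ))
  })
  expect_identical(sets[[1]], sets[[2]])
  expect_identical(sets[[1]], sets[[3]])
  expect_error(model_spec("frequency", "altitude"), "Unknown variable")
})

test_that("design data centers covariates and indexes the hierarchy", {
  tt <- toy_tables()
  md <- build_model_data(tt$daily, tt$weather, model_spec("frequency", "wind"))
  expect_lt(abs(mean(md$X[, "wind"])), 1e-9)
  expect_equal(md$X[, "wind"] + md$centers[["wind"]], tt$weather$max_wind_kmh,
    ignore_attr = TRUE
  )
  expect_equal(unique(md$X[, "wind"]), c(-10, 0, 10), ignore_attr = TRUE)

  # centering an already mean-zero covariate changes nothing
  wx0 <- tt$weather
  wx0$max_wind_kmh <- wx0$max_wind_kmh - mean(wx0$max_wind_kmh)
  md0 <- build_model_data(tt$daily, wx0, model_spec("frequency", "wind"))
  expect_equal(md0$X[, "wind"], md$X[, "wind"])
  expect_equal(md0$centers[["wind"]], 0)

  # a spec without weather variables carries no continuous columns
  md2 <- build_model_data(tt$daily, tt$weather, model_spec("duration", "reproductive"))
  expect_equal(ncol(md2$X), 0)
  expect_equal(md2$cond_levels, c("P", "L"))
  expect_true(all(md2$cond_idx %in% 1:2))

  # every individual maps to exactly one condition
  md3 <- build_model_data(
    tt$daily, tt$weather,
    model_spec("duration", c("reproductive", "individual"))
  )
  expect_equal(md3$ind_cond, c("L", "P", "P"))

  expect_error(
    build_model_data(tt$daily, tt$weather[-3, ], model_spec("frequency", "wind")),
    "2017-06-03"
  )
})

test_that("log-likelihood matches closed forms and a brute-force oracle", {
  tt <- toy_tables(n = 15, seed = 3)
  # Bernoulli at eta = 0
  md <- build_model_data(tt$daily, tt$weather, model_spec("frequency", character(0)))
  th <- make_theta(md, beta0 = 0)
  expect_equal(log_likelihood(th, md), 15 * log(0.5))

  # Normal with zero residuals and unit sigma
  daily_const <- tt$daily
  daily_const$duration_min <- 240
  mdn <- build_model_data(daily_const, tt$weather, model_spec("duration", character(0)))
  thn <- make_theta(mdn, beta0 = 240, sigma_resid = 1)
  expect_equal(log_likelihood(thn, mdn), -(15 / 2) * log(2 * pi))
  expect_error(
    log_likelihood(make_theta(mdn, sigma_resid = -1), mdn), "positive"
  )

  # random hierarchical instance vs per-observation sum
  set.seed(7)
  md4 <- build_model_data(
    tt$daily, tt$weather,
    model_spec("depth", c("reproductive", "individual", "wind", "precip"))
  )
  th4 <- make_theta(md4,
    beta0 = 25,
    slopes = c(wind = -0.1, precip = 0.2),
    b_cond = setNames(rnorm(2), md4$cond_levels),
    b_ind = setNames(rnorm(3), md4$ind_levels),
    sigma_resid = 3
  )
  eta_manual <- vapply(seq_len(md4$n), function(i) {
    25 + -0.1 * md4$X[i, "wind"] + 0.2 * md4$X[i, "precip"] +
      th4$b_cond[[md4$cond_idx[i]]] + th4$b_ind[[md4$ind_idx[i]]]
  }, numeric(1))
  oracle <- sum(dnorm(md4$y, eta_manual, 3, log = TRUE))
  expect_equal(log_likelihood(th4, md4), oracle)

  # adding a variable with coefficient zero leaves the likelihood unchanged
  md5 <- build_model_data(tt$daily, tt$weather, model_spec("frequency", "wind"))
  md6 <- build_model_data(tt$daily, tt$weather, model_spec("frequency", c("wind", "precip")))
  th5 <- make_theta(md5, beta0 = 0.4, slopes = c(wind = 0.05))
  th6 <- make_theta(md6, beta0 = 0.4, slopes = c(wind = 0.05, precip = 0))
  expect_equal(log_likelihood(th5, md5), log_likelihood(th6, md6))
})

test_that("log-prior matches closed forms and scales correctly", {
  tt <- toy_tables(n = 9, seed = 5)
  md <- build_model_data(tt$daily, tt$weather, model_spec("frequency", "wind"))
  th <- make_theta(md, beta0 = 0, slopes = c(wind = 0))
  expect_equal(
    log_prior(th, prior = prior_control(beta_sd = 1)),
    2 * dnorm(0, 0, 1, log = TRUE)
  )
  # doubling the prior SD lowers the density at 0 by log 2 per parameter
  expect_equal(
    log_prior(th, prior = prior_control(beta_sd = 1)) -
      log_prior(th, prior = prior_control(beta_sd = 2)),
    2 * log(2)
  )

  # hierarchical term-by-term oracle
  set.seed(11)
  mdh <- build_model_data(
    tt$daily, tt$weather,
    model_spec("duration", c("reproductive", "individual", "min_ta"))
  )
  th2 <- make_theta(mdh,
    beta0 = 300, slopes = c(min_ta = -5),
    b_cond = setNames(rnorm(2, 0, 30), mdh$cond_levels),
    b_ind = setNames(rnorm(3, 0, 50), mdh$ind_levels),
    sigma_cond = 40, sigma_ind = 60, sigma_resid = 120
  )
  pc <- prior_control(beta_sd = 100, sigma_scale = 25)
  oracle <- dnorm(300, 0, 100, log = TRUE) + dnorm(-5, 0, 100, log = TRUE) +
    sum(dnorm(th2$b_cond, 0, 40, log = TRUE)) +
    sum(dnorm(th2$b_ind, 0, 60, log = TRUE)) +
    sum(dcauchy(c(40, 60, 120), 0, 25, log = TRUE) + log(2))
  expect_equal(log_prior(th2, prior = pc), oracle)
  th_bad <- th2
  th_bad$sigma_ind <- 0
  expect_error(log_prior(th_bad, prior = pc), "positive")
})

test_that("logit and ilogit invert each other to numerical precision", {
  # Round-tripping through the probability scale is limited by double
  # precision once ilogit(x) rounds to within ~eps of 1: the absolute error
  # of the round trip grows like eps/(1 - p). Exact inversion to 1e-12 is
  # therefore checked where it is representable, and the upper tail is
  # checked against the same bound through the symmetric lower tail.
  x <- seq(-30, 8, by = 0.25)
  expect_lt(max(abs(logit(ilogit(x)) - x)), 1e-12)
  xt <- seq(8, 30, by = 0.25)
  expect_lt(max(abs(-logit(ilogit(-xt)) - xt)), 1e-12)
  expect_equal(ilogit(xt), 1 - ilogit(-xt), tolerance = 1e-15)
  p <- seq(0.001, 0.999, by = 0.001)
  expect_lt(max(abs(ilogit(logit(p)) - p)), 1e-12)
})

test_that("one individual per condition with zero deflections collapses to the condition model", {
  tt <- toy_tables(n = 12, seed = 13)
  tt$daily$individual_id <- tt$daily$condition # one individual per condition
  md_h <- build_model_data(
    tt$daily, tt$weather,
    model_spec("depth", c("reproductive", "individual"))
  )
  md_c <- build_model_data(tt$daily, tt$weather, model_spec("depth", "reproductive"))
  b <- setNames(c(1.5, -1.5), md_c$cond_levels)
  th_h <- make_theta(md_h,
    beta0 = 25, b_cond = b,
    b_ind = setNames(rep(0, 2), md_h$ind_levels), sigma_resid = 3
  )
  th_c <- make_theta(md_c, beta0 = 25, b_cond = b, sigma_resid = 3)
  expect_equal(log_likelihood(th_h, md_h), log_likelihood(th_c, md_c))
})
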