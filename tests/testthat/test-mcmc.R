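# intercept-only Normal data with a known conjugate posterior
conjugate_data <- function(n = 40, seed = 17, mu = 300, sigma = 80) {
  set.seed(seed)
  dates <- as.Date("2017-06-01") + seq_len(n) - 1
  daily <- tibble::tibble(
    individual_id = "P01", condition = "P", date = dates,
    torpid = TRUE, duration_min = rnorm(n, mu, sigma), depth_c = 25
  )
  weather <- tibble::tibble(
    date = dates, max_wind_kmh = 20, precip_mm = 0, min_ta = 10
  )
  build_model_data(daily, weather, model_spec("duration", character(0)))
}

test_that("the sampler recovers a conjugate Normal-mean posterior", {
  sigma <- 80
  md <- conjugate_data(sigma = sigma)
  fit <- sample_posterior(md,
    n_chains = 4, n_iter = 4000, burn_in = 1000, thin = 2, seed = 23,
    prior = prior_control(beta_sd = 100, sigma_scale = NULL),
    control = list(fixed = list(sigma_resid = sigma))
  )
  # closed form: precision n/sigma^2 + 1/100^2, prior mean 0
  prec <- md$n / sigma^2 + 1 / 100^2
  post_mean <- sum(md$y) / sigma^2 / prec
  post_sd <- sqrt(1 / prec)
  draws <- do.call(rbind, fit$samples)[, "beta0"]
  # MC standard error from between-chain spread of chain means
  chain_means <- purrr::map_dbl(fit$samples, ~ mean(.x[, "beta0"]))
  mcse <- sd(chain_means) / sqrt(length(chain_means))
  expect_lt(abs(mean(draws) - post_mean), 3 * mcse + 0.02 * post_sd)
  expect_lt(abs(sd(draws) / post_sd - 1), 0.1)
  # one free parameter: pD close to 1
  expect_lt(abs(fit$p_d - 1), 0.3)
  expect_lt(max(fit$rhat), 1.05)
})

test_that("a balanced logistic intercept centres on probability one half", {
  dates <- as.Date("2017-06-01") + 0:39
  daily <- tibble::tibble(
    individual_id = "P01", condition = "P", date = dates,
    torpid = rep(c(TRUE, FALSE), 20), duration_min = 0, depth_c = 25
  )
  weather <- tibble::tibble(
    date = dates, max_wind_kmh = 20, precip_mm = 0, min_ta = 10
  )
  md <- build_model_data(daily, weather, model_spec("frequency", character(0)))
  fit <- sample_posterior(md,
    n_chains = 2, n_iter = 3000, burn_in = 1000, thin = 2, seed = 29
  )
  med <- median(ilogit(do.call(rbind, fit$samples)[, "beta0"]))
  expect_lt(abs(med - 0.5), 0.05)
})

test_that("sampling is exactly reproducible from the seed", {
  md <- conjugate_data(n = 20)
  ctl <- list(rhat_warn = Inf) # short demonstration chains
  f1 <- sample_posterior(md, n_chains = 2, n_iter = 600, burn_in = 300, thin = 3, seed = 31, control = ctl)
  f2 <- sample_posterior(md, n_chains = 2, n_iter = 600, burn_in = 300, thin = 3, seed = 31, control = ctl)
  expect_identical(f1$samples, f2$samples)
  expect_identical(f1$dic, f2$dic)
  f3 <- sample_posterior(md, n_chains = 2, n_iter = 600, burn_in = 300, thin = 3, seed = 32, control = ctl)
  expect_false(identical(f1$samples, f3$samples))
})

test_that("sampler guards its preconditions", {
  md <- conjugate_data(n = 20)
  expect_error(
    sample_posterior(md, n_chains = 2, n_iter = 100, burn_in = 100, seed = 1),
    "exceed"
  )
  expect_error(
    sample_posterior(md, n_chains = 1, n_iter = 200, burn_in = 100, seed = 1),
    "chains"
  )
  bad <- conjugate_data(n = 20)
  bad$y[3] <- Inf
  expect_error(
    sample_posterior(bad, n_chains = 2, n_iter = 200, burn_in = 100, seed = 1),
    "Non-finite deviance"
  )
})

test_that("gelman_rubin behaves at its analytic edge cases", {
  set.seed(41)
  base <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(gelman_rubin(list(base, base)), c(a = 1, b = 1))

  c1 <- matrix(1, 50, 1, dimnames = list(NULL, "a"))
  c2 <- matrix(2, 50, 1, dimnames = list(NULL, "a"))
  expect_equal(gelman_rubin(list(c1, c2))[["a"]], Inf)
  expect_equal(gelman_rubin(list(c1, c1))[["a"]], 1)

  chains <- purrr::map(1:4, ~ matrix(rnorm(1000), 1000, 1, dimnames = list(NULL, "a")))
  expect_lt(gelman_rubin(chains)[["a"]], 1.01)

  expect_error(gelman_rubin(list(base)), "2 chains")
})

test_that("the DIC decomposition satisfies its identity", {
  md <- conjugate_data(n = 25, seed = 43)
  fit <- sample_posterior(md, n_chains = 2, n_iter = 1000, burn_in = 400, thin = 2, seed = 47,
    control = list(rhat_warn = Inf))
  expect_equal(fit$dic, fit$dbar + fit$p_d, tolerance = 1e-9)
  expect_equal(fit$dic - fit$dbar, fit$dbar - fit$d_at_mean, tolerance = 1e-9)
  expect_equal(fit$dic, 2 * fit$dbar - fit$d_at_mean, tolerance = 1e-9)
  # recomputing from the stored draws reproduces the stored values
  again <- compute_dic(fit)
  expect_equal(again$dic, fit$dic)
  expect_equal(again$p_d, fit$p_d)
})

test_that("fits persist to CSV samples and a JSON summary", {
  md <- conjugate_data(n = 20)
  fit <- sample_posterior(md,
    n_chains = 2, n_iter = 600, burn_in = 300, thin = 3, seed = 37,
    control = list(rhat_warn = Inf)
  )
  dir <- withr::local_tempdir()
  paths <- write_fit_csv(fit, dir, prefix = "toy")
  samples <- readr::read_csv(paths[["samples"]], show_col_types = FALSE)
  expect_equal(nrow(samples), 2 * nrow(fit$samples[[1]]))
  expect_true(all(c("chain", "draw", "beta0", "sigma_resid") %in% names(samples)))
  expect_equal(
    mean(samples$beta0),
    mean(do.call(rbind, reported_samples(fit, combine = FALSE))[, "beta0"])
  )
  summ <- jsonlite::read_json(paths[["summary"]])
  expect_equal(summ$dic, fit$dic)
  expect_equal(summ$p_d, fit$p_d)
  expect_equal(summ$settings$n_chains, 2)
})

test_that("posterior slope SD contracts like one over root n", {
  make_md <- function(n, seed) {
    set.seed(seed)
    dates <- as.Date("2017-06-01") + seq_len(n) - 1
    wind <- runif(n, 0, 40)
    daily <- tibble::tibble(
      individual_id = "P01", condition = "P", date = dates,
      torpid = TRUE, depth_c = 25,
      duration_min = 300 + 3 * (wind - mean(wind)) + rnorm(n, 0, 60)
    )
    weather <- tibble::tibble(
      date = dates, max_wind_kmh = wind, precip_mm = 0, min_ta = 10
    )
    build_model_data(daily, weather, model_spec("duration", "wind"))
  }
  sd_slope <- function(n, data_seed) {
    fit <- sample_posterior(make_md(n, data_seed),
      n_chains = 2, n_iter = 4000, burn_in = 1500, thin = 2, seed = 53
    )
    sd(do.call(rbind, fit$samples)[, "wind"])
  }
  # average two data replicates per size to tame design noise
  r1 <- mean(c(sd_slope(80, 1), sd_slope(80, 2)))
  r2 <- mean(c(sd_slope(160, 3), sd_slope(160, 4)))
  ratio <- r2 / r1
  expect_gt(ratio, 1 / sqrt(2) * 0.8)
  expect_lt(ratio, 1 / sqrt(2) * 1.2)
})
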