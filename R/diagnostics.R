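#' Gelman-Rubin potential scale reduction factor
#'
#' The classic PSRF computed per parameter from >= 2 chains:
#' `rhat = sqrt(((n-1)/n * W + B/n) / W)` with `W` the mean within-chain
#' variance and `B/n` the between-chain variance of the chain means. Values
#' are floored at 1 (the `(n-1)/n` term otherwise deflates the statistic
#' slightly below 1 for finite chains); chains with zero within-chain
#' variance but different levels return `Inf`, and chains constant at the
#' same value return 1.
#'
#' @param fit A [sample_posterior()] fit, or a list of draw matrices with
#'   identical column names (chains x (draws x parameters)).
#' @return Named numeric vector of rhat values.
#' @export
gelman_rubin <- function(fit) {
  mats <- if (inherits(fit, "torpor_fit")) fit$samples else fit
  if (!is.list(mats) || length(mats) < 2) {
    abort("At least 2 chains are required for the Gelman-Rubin diagnostic.")
  }
  n <- nrow(mats[[1]])
  if (n < 10) abort("At least 10 kept draws per chain are required.")
  params <- colnames(mats[[1]])
  vapply(params, function(p) {
    draws <- vapply(mats, function(m) m[, p], numeric(n))
    W <- mean(apply(draws, 2, var))
    B_over_n <- var(colMeans(draws)) # between-chain variance of means
    if (W == 0) {
      return(if (B_over_n == 0) 1 else Inf)
    }
    max(1, sqrt(((n - 1) / n * W + B_over_n) / W))
  }, numeric(1))
}

#' Deviance information criterion
#'
#' `DIC = dbar + pD` with `dbar` the posterior mean of the deviance
#' `D(theta) = -2 log L(theta)`, `pD = dbar - D(theta_bar)` the effective
#' number of parameters, and `theta_bar` the posterior mean of the
#' unconstrained parameters (the standard plug-in; SD components are
#' averaged on the log scale). Lower DIC indicates the more explanatory
#' model.
#'
#' @param fit A [sample_posterior()] fit.
#' @param data The model data (defaults to the one stored in the fit).
#' @return A list with `dbar`, `d_at_mean`, `p_d`, `dic`.
#' @export
compute_dic <- function(fit, data = fit$data) {
  ll <- unlist(fit$loglik)
  dbar <- mean(-2 * ll)
  all_draws <- do.call(rbind, fit$samples)
  theta_bar <- colMeans(all_draws)
  th <- flat_to_theta(theta_bar, data, fit$fixed %||% list())
  d_at_mean <- -2 * log_likelihood(th, data)
  p_d <- dbar - d_at_mean
  list(dbar = dbar, d_at_mean = d_at_mean, p_d = p_d, dic = dbar + p_d)
}

#' Highest density interval from posterior samples
#'
#' The shortest contiguous interval containing `mass` of the draws: with
#' `m = ceiling(mass * n)`, scans every window of `m` consecutive sorted
#' samples and returns the narrowest.
#'
#' @param samples Numeric vector of posterior draws (>= `min_n`).
#' @param mass Probability mass to cover (default 0.95).
#' @param min_n Minimum number of draws required.
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' hdi(rnorm(1000))
#' @export
hdi <- function(samples, mass = 0.95, min_n = 100) {
  samples <- samples[is.finite(samples)]
  n <- length(samples)
  if (n < min_n) {
    abort(sprintf("Need at least %d samples for an HDI; got %d.", min_n, n))
  }
  check_number(mass, "mass", 1e-6, 1)
  s <- sort(samples)
  m <- ceiling(mass * n)
  if (m >= n) {
    return(c(lower = s[1], upper = s[n]))
  }
  starts <- seq_len(n - m + 1L)
  widths <- s[starts + m - 1L] - s[starts]
  i <- which.min(widths)
  c(lower = s[i], upper = s[i + m - 1L])
}
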