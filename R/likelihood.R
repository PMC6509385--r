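#' Parameter vector for a candidate model
#'
#' The sampler's (unconstrained) parameterization: a grand intercept
#' `beta0`, one slope per included centered covariate, condition deflections
#' `b_cond` (drawn from Normal(0, sigma_cond^2)), individual deflections
#' `b_ind` (Normal(0, sigma_ind^2), i.e. deflections from their condition's
#' mean since the linear predictor carries both terms), and the variance
#' components. Reported estimates are recentred post hoc so that deflections
#' sum to zero and `beta0` is the grand mean of the response across groups.
#'
#' @param data A [build_model_data()] object.
#' @param beta0,slopes,b_cond,b_ind,sigma_cond,sigma_ind,sigma_resid
#'   Components; defaults give a neutral starting point.
#' @return A list of class `"torpor_theta"`.
#' @export
make_theta <- function(data, beta0 = NULL, slopes = NULL, b_cond = NULL,
                       b_ind = NULL, sigma_cond = 1, sigma_ind = 1,
                       sigma_resid = 1) {
  ybar <- mean(data$y)
  if (is.null(beta0)) {
    beta0 <- if (data$family == "bernoulli") {
      logit(min(max(ybar, 0.02), 0.98))
    } else {
      ybar
    }
  }
  if (is.null(slopes)) slopes <- setNames(rep(0, ncol(data$X)), colnames(data$X))
  if (is.null(b_cond) && !is.null(data$cond_levels)) {
    b_cond <- setNames(rep(0, length(data$cond_levels)), data$cond_levels)
  }
  if (is.null(b_ind) && !is.null(data$ind_levels)) {
    b_ind <- setNames(rep(0, length(data$ind_levels)), data$ind_levels)
  }
  structure(
    list(
      beta0 = beta0, slopes = slopes, b_cond = b_cond, b_ind = b_ind,
      sigma_cond = if (!is.null(b_cond)) sigma_cond else NULL,
      sigma_ind = if (!is.null(b_ind)) sigma_ind else NULL,
      sigma_resid = if (data$family == "normal") sigma_resid else NULL
    ),
    class = "torpor_theta"
  )
}

#' Linear predictor for a parameter vector
#'
#' `eta_i = beta0 + b_cond[j(i)] + b_ind[k(i)] + X beta`, restricted to the
#' terms the model includes.
#'
#' @param theta A [make_theta()] list.
#' @param data A [build_model_data()] object.
#' @return Numeric vector of length `data$n`.
#' @export
linear_predictor <- function(theta, data) {
  eta <- rep(theta$beta0, data$n)
  if (length(theta$slopes)) {
    eta <- eta + drop(data$X[, names(theta$slopes), drop = FALSE] %*% theta$slopes)
  }
  if (!is.null(theta$b_cond)) eta <- eta + theta$b_cond[data$cond_idx]
  if (!is.null(theta$b_ind)) eta <- eta + theta$b_ind[data$ind_idx]
  unname(eta)
}

#' Model log-likelihood
#'
#' Sum of Bernoulli(`ilogit(eta_i)`) log-masses (frequency models) or
#' Normal(`eta_i`, `sigma_resid`) log-densities (duration/depth models).
#'
#' @inheritParams linear_predictor
#' @param spec Optional [model_spec()]; defaults to the one inside `data`.
#' @return A single log-density value.
#' @export
log_likelihood <- function(theta, data, spec = data$spec) {
  eta <- linear_predictor(theta, data)
  loglik_eta(eta, data, theta$sigma_resid)
}

# likelihood given a precomputed linear predictor (the sampler's hot path)
loglik_eta <- function(eta, data, sigma_resid = NULL, rows = NULL) {
  y <- data$y
  if (!is.null(rows)) {
    y <- y[rows]
    eta <- eta[rows]
  }
  if (data$family == "bernoulli") {
    sum(dbinom(y, 1, ilogit(eta), log = TRUE))
  } else {
    if (is.null(sigma_resid) || sigma_resid <= 0) {
      abort("`sigma_resid` must be positive for Normal-family models.")
    }
    sum(dnorm(y, eta, sigma_resid, log = TRUE))
  }
}

#' Prior settings
#'
#' Weakly informative priors: Normal(0, `beta_sd`^2) on the intercept and
#' slopes (on the modeled scale) and half-Cauchy(`sigma_scale`) on each
#' standard-deviation component. By default `sigma_scale` is set by the
#' sampler to five times the response SD.
#'
#' @param beta_sd Prior SD for intercept and slopes.
#' @param sigma_scale Half-Cauchy scale for SD components (single value
#'   recycled to condition/individual/residual components).
#' @return A list.
#' @export
prior_control <- function(beta_sd = 100, sigma_scale = 25) {
  list(beta_sd = beta_sd, sigma_scale = sigma_scale)
}

half_cauchy_log <- function(x, scale) {
  if (any(x <= 0)) return(-Inf)
  sum(dcauchy(x, 0, scale, log = TRUE)) + length(x) * log(2)
}

#' Model log-prior
#'
#' Normal(0, `beta_sd`^2) on `beta0` and slopes; hierarchical Normals on the
#' deflections (`b_cond[j] ~ N(0, sigma_cond^2)`,
#' `b_ind[k] ~ N(0, sigma_ind^2)` as deflections from the condition mean);
#' half-Cauchy priors on the SD components.
#'
#' @inheritParams log_likelihood
#' @param prior A [prior_control()] list.
#' @return A single log-density value.
#' @export
log_prior <- function(theta, spec = NULL, prior = prior_control()) {
  for (s in c("sigma_cond", "sigma_ind", "sigma_resid")) {
    if (!is.null(theta[[s]]) && theta[[s]] <= 0) {
      abort(sprintf("`%s` must be positive.", s))
    }
  }
  lp <- dnorm(theta$beta0, 0, prior$beta_sd, log = TRUE) +
    sum(dnorm(theta$slopes, 0, prior$beta_sd, log = TRUE))
  if (!is.null(theta$b_cond)) {
    lp <- lp + sum(dnorm(theta$b_cond, 0, theta$sigma_cond, log = TRUE)) +
      half_cauchy_log(theta$sigma_cond, prior$sigma_scale)
  }
  if (!is.null(theta$b_ind)) {
    lp <- lp + sum(dnorm(theta$b_ind, 0, theta$sigma_ind, log = TRUE)) +
      half_cauchy_log(theta$sigma_ind, prior$sigma_scale)
  }
  if (!is.null(theta$sigma_resid)) {
    lp <- lp + half_cauchy_log(theta$sigma_resid, prior$sigma_scale)
  }
  lp
}
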