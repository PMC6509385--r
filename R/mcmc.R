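#' Sample the posterior of a candidate model
#'
#' Adaptive random-walk Metropolis-within-Gibbs. Location parameters
#' (intercept, slopes, condition and individual deflections) are updated one
#' block at a time with Gaussian proposals whose scales adapt toward ~30%
#' acceptance during burn-in (adaptation is frozen afterwards, so the kept
#' chain is a valid Markov chain). Standard-deviation components are updated
#' by random-walk Metropolis on the log scale (with the Jacobian term), as
#' the half-Cauchy priors admit no conjugate draw. Deflection updates
#' re-evaluate the likelihood only on the rows of the affected group, so a
#' full sweep costs O(n) regardless of the number of individuals.
#'
#' Chains are initialized at the data mean with per-chain jitter, and every
#' chain's RNG stream derives from `seed`, so results are exactly
#' reproducible.
#'
#' @param data A [build_model_data()] object.
#' @param n_chains Number of chains (>= 2 for convergence diagnostics).
#' @param n_iter Total iterations per chain.
#' @param burn_in Burn-in iterations discarded (must be < `n_iter`).
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param seed Integer seed.
#' @param prior A [prior_control()]; when `sigma_scale` is `NULL` it is set
#'   to 5 x SD of the response.
#' @param control Optional list: `fixed` (named list of parameters to hold
#'   fixed, e.g. `list(sigma_resid = 1)` for conjugate checks),
#'   `target_accept` (default 0.3), `rhat_warn` (default 1.1, `Inf`
#'   disables the convergence warning).
#' @return A list of class `"torpor_fit"`: `samples` (list of kept-draw
#'   matrices, one per chain, unconstrained scale), `loglik` (kept
#'   log-likelihoods), `acceptance` rates per parameter, `rhat`, and the DIC
#'   decomposition `dbar`, `d_at_mean`, `p_d`, `dic`.
#' @examples
#' daily <- tibble::tibble(
#'   individual_id = "a", condition = "P",
#'   date = as.Date("2017-06-01") + 0:19,
#'   torpid = rep(c(TRUE, FALSE), 10), duration_min = 0, depth_c = 30
#' )
#' weather <- tibble::tibble(
#'   date = as.Date("2017-06-01") + 0:19,
#'   max_wind_kmh = 20, precip_mm = 0, min_ta = 10
#' )
#' md <- build_model_data(daily, weather, model_spec("frequency", "wind"))
#' fit <- sample_posterior(md, n_chains = 2, n_iter = 400, burn_in = 200,
#'                         thin = 2, seed = 1)
#' glance(fit)
#' @export
sample_posterior <- function(data, n_chains = 4, n_iter = 20000,
                             burn_in = 10000, thin = 5, seed = 1,
                             prior = prior_control(sigma_scale = NULL),
                             control = list()) {
  stopifnot(inherits(data, "torpor_model_data"))
  if (n_iter <= burn_in) abort("`n_iter` must exceed `burn_in`.")
  if (n_chains < 2) abort("Use at least 2 chains (convergence diagnostics).")
  if (any(!is.finite(data$y))) {
    abort("Non-finite deviance: the response vector contains non-finite values.")
  }
  target <- control$target_accept %||% 0.3
  fixed <- control$fixed %||% list()
  if (is.null(prior$sigma_scale)) {
    prior$sigma_scale <- max(5 * sd(data$y), 1e-3)
  }

  layout <- param_layout(data, fixed)
  kept_idx <- seq(burn_in + thin, n_iter, by = thin)

  chains <- vector("list", n_chains)
  lls <- vector("list", n_chains)
  acc_tot <- att_tot <- setNames(numeric(length(layout$names)), layout$names)

  for (ch in seq_len(n_chains)) {
    res <- withr::with_seed(
      child_seed(seed, 7000L + ch),
      run_chain(data, layout, prior, fixed, n_iter, burn_in, kept_idx, target)
    )
    chains[[ch]] <- res$kept
    lls[[ch]] <- res$ll
    acc_tot <- acc_tot + res$acc
    att_tot <- att_tot + res$att
  }

  fit <- structure(
    list(
      samples = chains, loglik = lls,
      acceptance = acc_tot / pmax(att_tot, 1),
      param_names = layout$names, data = data, spec = data$spec,
      prior = prior, fixed = fixed, seed = seed,
      n_chains = n_chains, n_iter = n_iter, burn_in = burn_in, thin = thin
    ),
    class = "torpor_fit"
  )
  fit$rhat <- gelman_rubin(fit)
  fit[c("dbar", "d_at_mean", "p_d", "dic")] <- compute_dic(fit, data)

  rhat_warn <- control$rhat_warn %||% 1.1
  bad <- fit$rhat[is.finite(fit$rhat) & fit$rhat > rhat_warn]
  if (length(bad)) {
    warn(sprintf(
      "Convergence: rhat > %.2f for %s", rhat_warn,
      paste(sprintf("%s (%.2f)", names(bad), bad), collapse = ", ")
    ))
  }
  fit
}

# Names, block structure and row indices for the flat parameter vector
param_layout <- function(data, fixed = list()) {
  nm <- "beta0"
  blocks <- list(list(kind = "beta0", name = "beta0", rows = NULL))
  for (v in colnames(data$X)) {
    nm <- c(nm, v)
    blocks[[length(blocks) + 1L]] <- list(kind = "slope", name = v, rows = NULL)
  }
  if (!is.null(data$cond_levels)) {
    for (j in seq_along(data$cond_levels)) {
      pn <- paste0("cond:", data$cond_levels[j])
      nm <- c(nm, pn)
      blocks[[length(blocks) + 1L]] <- list(
        kind = "cond", name = pn, j = j, rows = which(data$cond_idx == j)
      )
    }
  }
  if (!is.null(data$ind_levels)) {
    for (k in seq_along(data$ind_levels)) {
      pn <- paste0("ind:", data$ind_levels[k])
      nm <- c(nm, pn)
      blocks[[length(blocks) + 1L]] <- list(
        kind = "ind", name = pn, k = k, rows = which(data$ind_idx == k)
      )
    }
  }
  for (s in c("sigma_cond", "sigma_ind", "sigma_resid")) {
    needed <- switch(s,
      sigma_cond = !is.null(data$cond_levels),
      sigma_ind = !is.null(data$ind_levels),
      sigma_resid = data$family == "normal"
    )
    if (needed && is.null(fixed[[s]])) {
      pn <- paste0("log_", s)
      nm <- c(nm, pn)
      blocks[[length(blocks) + 1L]] <- list(kind = s, name = pn, rows = NULL)
    }
  }
  list(names = nm, blocks = blocks)
}

run_chain <- function(data, layout, prior, fixed, n_iter, burn_in, kept_idx,
                      target) {
  nm <- layout$names
  npar <- length(nm)
  par <- setNames(numeric(npar), nm)
  ybar <- mean(data$y)
  beta0_start <- if (data$family == "bernoulli") {
    logit(min(max(ybar, 0.02), 0.98))
  } else {
    ybar
  }
  par["beta0"] <- beta0_start +
    rnorm(1, 0, if (data$family == "bernoulli") 0.2 else 0.1 * max(sd(data$y), 1))
  sd_y <- max(sd(data$y), 0.1)
  for (s in c("log_sigma_cond", "log_sigma_ind", "log_sigma_resid")) {
    if (s %in% nm) par[s] <- log(sd_y) + rnorm(1, 0, 0.2)
  }

  cond_names <- nm[startsWith(nm, "cond:")]
  ind_names <- nm[startsWith(nm, "ind:")]

  get_sigma <- function(s) {
    if (!is.null(fixed[[s]])) return(fixed[[s]])
    ln <- paste0("log_", s)
    if (ln %in% nm) exp(par[[ln]]) else NULL
  }

  eta <- rep(par[["beta0"]], data$n)
  # (deflections and slopes start at 0, so eta is just the intercept)

  scales <- setNames(rep(0.5, npar), nm)
  scales[startsWith(nm, "log_")] <- 0.4
  acc <- att <- batch_acc <- batch_att <- setNames(numeric(npar), nm)

  kept <- matrix(NA_real_, length(kept_idx), npar, dimnames = list(NULL, nm))
  ll_kept <- numeric(length(kept_idx))
  kpos <- 1L

  sig_resid <- get_sigma("sigma_resid")
  if (!is.finite(loglik_eta(eta, data, sig_resid))) {
    abort("Non-finite deviance at initialization (block beta0).")
  }

  for (it in seq_len(n_iter)) {
    adapting <- it <= burn_in
    for (b in layout$blocks) {
      p <- b$name
      d <- rnorm(1, 0, scales[[p]])
      batch_att[p] <- batch_att[p] + 1
      att[p] <- att[p] + 1
      accepted <- FALSE

      if (b$kind %in% c("beta0", "slope", "cond", "ind")) {
        rows <- b$rows
        if (b$kind == "beta0") {
          eta_new <- eta + d
          lp_old <- dnorm(par[[p]], 0, prior$beta_sd, log = TRUE)
          lp_new <- dnorm(par[[p]] + d, 0, prior$beta_sd, log = TRUE)
        } else if (b$kind == "slope") {
          eta_new <- eta + d * data$X[, p]
          lp_old <- dnorm(par[[p]], 0, prior$beta_sd, log = TRUE)
          lp_new <- dnorm(par[[p]] + d, 0, prior$beta_sd, log = TRUE)
        } else {
          sig <- if (b$kind == "cond") get_sigma("sigma_cond") else get_sigma("sigma_ind")
          eta_new <- eta
          eta_new[rows] <- eta[rows] + d
          lp_old <- dnorm(par[[p]], 0, sig, log = TRUE)
          lp_new <- dnorm(par[[p]] + d, 0, sig, log = TRUE)
        }
        ll_old <- loglik_eta(eta, data, sig_resid, rows = rows)
        ll_new <- loglik_eta(eta_new, data, sig_resid, rows = rows)
        if (!is.finite(ll_new) && !is.finite(ll_old)) {
          abort(sprintf("Non-finite deviance in parameter block `%s`.", p))
        }
        if (log(runif(1)) < (ll_new + lp_new) - (ll_old + lp_old)) {
          par[p] <- par[[p]] + d
          eta <- eta_new
          accepted <- TRUE
        }
      } else {
        # log-scale sigma update
        s <- b$kind
        old_ls <- par[[p]]
        new_ls <- old_ls + d
        old_s <- exp(old_ls)
        new_s <- exp(new_ls)
        delta <- half_cauchy_log(new_s, prior$sigma_scale) -
          half_cauchy_log(old_s, prior$sigma_scale) + (new_ls - old_ls)
        if (s == "sigma_cond") {
          vals <- par[cond_names]
          delta <- delta + sum(dnorm(vals, 0, new_s, log = TRUE)) -
            sum(dnorm(vals, 0, old_s, log = TRUE))
        } else if (s == "sigma_ind") {
          vals <- par[ind_names]
          delta <- delta + sum(dnorm(vals, 0, new_s, log = TRUE)) -
            sum(dnorm(vals, 0, old_s, log = TRUE))
        } else {
          delta <- delta + loglik_eta(eta, data, new_s) -
            loglik_eta(eta, data, old_s)
        }
        if (is.finite(delta) && log(runif(1)) < delta) {
          par[p] <- new_ls
          if (s == "sigma_resid") sig_resid <- new_s
          accepted <- TRUE
        }
      }

      if (accepted) {
        acc[p] <- acc[p] + 1
        batch_acc[p] <- batch_acc[p] + 1
      }
    }

    if (adapting && it %% 50 == 0) {
      nb <- it / 50
      step <- min(0.25, 1 / sqrt(nb))
      rate <- batch_acc / pmax(batch_att, 1)
      scales <- scales * exp((rate - target) * step)
      batch_acc[] <- 0
      batch_att[] <- 0
    }

    if (kpos <= length(kept_idx) && it == kept_idx[kpos]) {
      kept[kpos, ] <- par
      ll_kept[kpos] <- loglik_eta(eta, data, sig_resid)
      kpos <- kpos + 1L
    }
  }

  list(kept = kept, ll = ll_kept, acc = acc, att = att)
}

# Rebuild a theta list from a flat (unconstrained) parameter vector
flat_to_theta <- function(par, data, fixed = list()) {
  nms <- names(par)
  slopes <- par[intersect(colnames(data$X), nms)]
  cond <- par[startsWith(nms, "cond:")]
  names(cond) <- sub("^cond:", "", names(cond))
  ind <- par[startsWith(nms, "ind:")]
  names(ind) <- sub("^ind:", "", names(ind))
  gs <- function(s) {
    if (!is.null(fixed[[s]])) return(fixed[[s]])
    ln <- paste0("log_", s)
    if (ln %in% nms) exp(par[[ln]]) else NULL
  }
  structure(
    list(
      beta0 = par[["beta0"]], slopes = slopes,
      b_cond = if (length(cond)) cond else NULL,
      b_ind = if (length(ind)) ind else NULL,
      sigma_cond = if (length(cond)) gs("sigma_cond") else NULL,
      sigma_ind = if (length(ind)) gs("sigma_ind") else NULL,
      sigma_resid = if (data$family == "normal") gs("sigma_resid") else NULL
    ),
    class = "torpor_theta"
  )
}

#' Posterior samples on the reporting scale
#'
#' Converts the sampler's unconstrained draws to the reporting
#' parameterization: condition and individual deflections are recentred to
#' sum to zero, their means are absorbed into `beta0` (so `beta0` is the
#' grand mean of the response across groups), and SD components are
#' returned on the natural scale.
#'
#' @param fit A [sample_posterior()] fit.
#' @param combine Bind chains into one matrix (default) or return a list.
#' @return A matrix (or list of matrices) of reported draws.
#' @export
reported_samples <- function(fit, combine = TRUE) {
  conv <- function(m) {
    nms <- colnames(m)
    out <- m
    cond_cols <- nms[startsWith(nms, "cond:")]
    ind_cols <- nms[startsWith(nms, "ind:")]
    if (length(cond_cols)) {
      cm <- rowMeans(m[, cond_cols, drop = FALSE])
      out[, cond_cols] <- m[, cond_cols] - cm
      out[, "beta0"] <- out[, "beta0"] + cm
    }
    if (length(ind_cols)) {
      im <- rowMeans(m[, ind_cols, drop = FALSE])
      out[, ind_cols] <- m[, ind_cols] - im
      out[, "beta0"] <- out[, "beta0"] + im
    }
    for (ln in nms[startsWith(nms, "log_sigma")]) {
      out[, ln] <- exp(m[, ln])
    }
    colnames(out) <- sub("^log_", "", colnames(out))
    out
  }
  mats <- map(fit$samples, conv)
  if (combine) do.call(rbind, mats) else mats
}

#' @export
print.torpor_fit <- function(x, ...) {
  cat(sprintf(
    "<torpor_fit> %s ~ %s\n  %d chains x %d kept draws; DIC %.2f (pD %.2f); max rhat %.3f\n",
    x$spec$response, x$spec$label, x$n_chains, nrow(x$samples[[1]]),
    x$dic, x$p_d, max(x$rhat, na.rm = TRUE)
  ))
  invisible(x)
}
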