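#' Tidy a posterior fit
#'
#' One row per reported parameter: posterior mean, SD, 95% HDI and rhat
#' (rhat is computed on the unconstrained scale, where the chains actually
#' move).
#'
#' @param x A [sample_posterior()] fit.
#' @param hdi_mass Mass of the reported HDI.
#' @param ... Unused.
#' @return A tibble `term`, `estimate`, `std.error`, `hdi_lo`, `hdi_hi`,
#'   `rhat`.
#' @exportS3Method generics::tidy
#' @export
tidy.torpor_fit <- function(x, hdi_mass = 0.95, ...) {
  draws <- reported_samples(x)
  raw_rhat <- x$rhat
  names(raw_rhat) <- sub("^log_", "", names(raw_rhat))
  list_rbind(map(colnames(draws), function(p) {
    h <- hdi(draws[, p], mass = hdi_mass, min_n = 10)
    tibble(
      term = p,
      estimate = mean(draws[, p]),
      std.error = sd(draws[, p]),
      hdi_lo = h[["lower"]],
      hdi_hi = h[["upper"]],
      rhat = unname(raw_rhat[p])
    )
  }))
}

#' Fit-level summary
#'
#' @param x A [sample_posterior()] fit.
#' @param ... Unused.
#' @return A one-row tibble: model label, n, chains, kept draws, `dbar`,
#'   `p_d`, `dic`, max rhat, min/mean acceptance.
#' @exportS3Method generics::glance
#' @export
glance.torpor_fit <- function(x, ...) {
  tibble(
    model = x$spec$label,
    response = x$spec$response,
    n = x$data$n,
    n_chains = x$n_chains,
    n_kept = nrow(x$samples[[1]]) * x$n_chains,
    dbar = x$dbar,
    p_d = x$p_d,
    dic = x$dic,
    max_rhat = max(x$rhat, na.rm = TRUE),
    mean_accept = mean(x$acceptance)
  )
}

#' Tidy a rank table (drops the fit column for printing/export)
#'
#' @param x A [rank_models()] table.
#' @param ... Unused.
#' @return A plain tibble of the ranking columns.
#' @exportS3Method generics::tidy
#' @export
tidy.torpor_rank_table <- function(x, ...) {
  out <- as_tibble(x)
  out$variables <- map_chr(out$variables, ~ paste(.x, collapse = "+"))
  out[setdiff(names(out), "fit")]
}
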