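#' Persist a posterior fit as CSV samples plus a JSON summary
#'
#' Writes `samples.csv` (one row per kept draw with `chain` and `draw`
#' columns, parameters on the reporting scale) and `summary.json` (model
#' label, response, deviance decomposition, rhat and acceptance per
#' parameter, seed and sampler settings) into `dir`. The pair is the
#' plain-text, tool-agnostic record of a fit; `readRDS`-free downstream
#' tools can consume it.
#'
#' @param fit A [sample_posterior()] fit.
#' @param dir Output directory (created if needed).
#' @param prefix Optional file-name prefix (useful when persisting several
#'   fits into one directory).
#' @return Invisibly, the two file paths.
#' @export
write_fit_csv <- function(fit, dir, prefix = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stem <- if (is.null(prefix)) "" else paste0(prefix, "_")
  mats <- reported_samples(fit, combine = FALSE)
  tab <- list_rbind(purrr::imap(mats, function(m, ch) {
    out <- as_tibble(as.data.frame(m))
    out |> mutate(chain = as.integer(ch), draw = dplyr::row_number(), .before = 1)
  }))
  samples_path <- file.path(dir, paste0(stem, "samples.csv"))
  readr::write_csv(tab, samples_path)

  summary_path <- file.path(dir, paste0(stem, "summary.json"))
  jsonlite::write_json(
    list(
      model = fit$spec$label,
      response = fit$spec$response,
      n = fit$data$n,
      dbar = fit$dbar, d_at_mean = fit$d_at_mean, p_d = fit$p_d,
      dic = fit$dic,
      rhat = as.list(fit$rhat),
      acceptance = as.list(fit$acceptance),
      seed = fit$seed,
      settings = list(
        n_chains = fit$n_chains, n_iter = fit$n_iter,
        burn_in = fit$burn_in, thin = fit$thin,
        prior = fit$prior, fixed = fit$fixed
      )
    ),
    summary_path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(c(samples = samples_path, summary = summary_path))
}
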