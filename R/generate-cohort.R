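#' Simulate a cohort of tracked individuals with known effects
#'
#' Draws one individual-level duration and depth effect per bat around its
#' reproductive condition's mean offset (SD `sigma_individual`), and assigns
#' each individual a contiguous tracking window of dates. Conditions occupy
#' staggered blocks of the season in phenological order (NOP early spring,
#' then P, NR, L, PL), as in a field season where reproductive classes are
#' sampled as they occur.
#'
#' @param n_per_condition Named integer vector of individuals per condition;
#'   names must be among P, L, PL, NR, NOP. The default matches a cohort of
#'   11 pregnant, 11 lactating, 8 post-lactating, 2 nonreproductive and 4
#'   not-obviously-pregnant females.
#' @param params A [truth_params()] object.
#' @return A tibble of class `"torpor_cohort"`, one row per individual:
#'   `individual_id`, `condition`, `dur_effect`, `depth_effect`,
#'   `start_day`, `n_days` (day indices into the simulated season). The
#'   ground-truth table is the recovery-test reference.
#' @examples
#' cohort <- generate_cohort(params = truth_params(seed = 7))
#' nrow(cohort)
#' @export
generate_cohort <- function(n_per_condition = c(P = 11, L = 11, PL = 8, NR = 2, NOP = 4),
                            params = truth_params()) {
  if (is.null(names(n_per_condition)) ||
    !all(names(n_per_condition) %in% condition_labels())) {
    abort("`n_per_condition` must be named with labels among P, L, PL, NR, NOP.")
  }
  if (any(n_per_condition < 0) || sum(n_per_condition) < 1) {
    abort("`n_per_condition` must be nonnegative with at least one individual.")
  }
  n_per_condition <- n_per_condition[n_per_condition > 0]

  eff <- params$condition_effects
  # phenological order across the season
  order_used <- intersect(c("NOP", "P", "NR", "L", "PL"), names(n_per_condition))
  n_blocks <- length(order_used)
  block_len <- params$season_days / n_blocks

  withr::with_seed(child_seed(params$seed, 202L), {
    rows <- purrr::imap(
      setNames(seq_len(n_blocks), order_used),
      function(block, cond) {
        n <- n_per_condition[[cond]]
        e <- eff[eff$condition == cond, ]
        lo <- floor((block - 1) * block_len) + 1L
        hi <- ceiling(block * block_len)
        day_choices <- seq(params$days_range[1], params$days_range[2])
        n_days <- day_choices[sample.int(length(day_choices), n, replace = TRUE)]
        start_max <- pmax(lo, hi - n_days + 1L)
        tibble(
          condition = cond,
          dur_effect = rnorm(n, e$dur_offset, params$sigma_individual[["duration"]]),
          depth_effect = rnorm(n, e$depth_offset, params$sigma_individual[["depth"]]),
          start_day = purrr::map2_int(
            rep(lo, n), start_max,
            ~ if (.y <= .x) .x else sample(seq(.x, .y), 1L)
          ),
          n_days = n_days
        )
      }
    )
    cohort <- list_rbind(rows)
    cohort <- cohort |>
      mutate(
        individual_id = sprintf("%s%02d", .data$condition,
          stats::ave(seq_len(nrow(cohort)), cohort$condition, FUN = seq_along)
        ),
        .before = 1
      )
    class(cohort) <- c("torpor_cohort", class(cohort))
    attr(cohort, "params") <- params
    cohort
  })
}
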