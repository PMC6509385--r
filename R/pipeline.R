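#' Configure an end-to-end torpor analysis run
#'
#' Bundles the inputs (telemetry/ambient/weather CSV paths, or generator
#' parameters for a synthetic run), the torpor extraction rule constants,
#' the MCMC settings, the candidate-set override and the master seed for a
#' [run_torpor_pipeline()] call. Rule constants default to the analysis
#' definitions: 80th-percentile threshold minus 3 deg C, bouts of >= 2
#' consecutive readings, bat days missing > 60 min excluded.
#'
#' @param telemetry,ambient,weather CSV paths (all three, for a real-data
#'   run) or `NULL` to simulate.
#' @param params [truth_params()] for a synthetic run; its seed is replaced
#'   by `seed`.
#' @param n_per_condition Cohort sizes for a synthetic run.
#' @param percentile,offset_c,min_run,max_missing_min,cadence_min Torpor
#'   rule constants.
#' @param responses Which responses to model.
#' @param candidates Either `NULL` (the full 14-model set) or a list of
#'   variable-name vectors overriding it.
#' @param n_chains,n_iter,burn_in,thin MCMC settings per model fit.
#' @param prior_beta_sd,prior_sigma_scale Prior settings forwarded to
#'   [prior_control()]; `prior_sigma_scale = NULL` uses 5 x SD of each
#'   response.
#' @param level,threshold Confidence-set level and normalized-variable-weight
#'   cutoff.
#' @param outdir Output directory for tables, fits and the report.
#' @param seed Master seed; all stage seeds derive from it.
#' @param quiet Suppress stage logging.
#' @return A list of class `"torpor_pipeline_config"`.
#' @export
pipeline_config <- function(telemetry = NULL, ambient = NULL, weather = NULL,
                            params = truth_params(),
                            n_per_condition = c(P = 11, L = 11, PL = 8, NR = 2, NOP = 4),
                            percentile = 0.80, offset_c = 3, min_run = 2,
                            max_missing_min = 60, cadence_min = 10,
                            responses = c("frequency", "duration", "depth"),
                            candidates = NULL,
                            n_chains = 4, n_iter = 8000, burn_in = 4000,
                            thin = 4,
                            prior_beta_sd = 100, prior_sigma_scale = NULL,
                            level = 0.95, threshold = 0.60,
                            outdir = tempfile("torpor_run_"), seed = 1,
                            quiet = FALSE) {
  paths <- c(telemetry = telemetry, ambient = ambient, weather = weather)
  synthetic <- length(paths) == 0
  if (!synthetic && length(paths) != 3) {
    abort("Provide all three of `telemetry`, `ambient`, `weather`, or none.")
  }
  if (!synthetic) {
    missing <- paths[!file.exists(paths)]
    if (length(missing)) {
      abort(sprintf(
        "Input file(s) not found: %s",
        paste(sprintf("%s (%s)", names(missing), missing), collapse = ", ")
      ))
    }
  }
  responses <- match.arg(responses, several.ok = TRUE)
  params$seed <- as.integer(seed)
  structure(
    list(
      telemetry = telemetry, ambient = ambient, weather = weather,
      synthetic = synthetic, params = params,
      n_per_condition = n_per_condition,
      rules = list(
        percentile = percentile, offset_c = offset_c, min_run = min_run,
        max_missing_min = max_missing_min, cadence_min = cadence_min
      ),
      responses = responses, candidates = candidates,
      mcmc = list(
        n_chains = n_chains, n_iter = n_iter, burn_in = burn_in, thin = thin
      ),
      prior = list(beta_sd = prior_beta_sd, sigma_scale = prior_sigma_scale),
      level = level, threshold = threshold,
      outdir = outdir, seed = as.integer(seed), quiet = quiet
    ),
    class = "torpor_pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; unknown keys
#' are rejected. `params` may be a mapping of [truth_params()] arguments.
#'
#' @param path YAML file.
#' @return A [pipeline_config()] object.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$params)) {
    if (!is.null(raw$params$condition_effects)) {
      raw$params$condition_effects <- as_tibble(raw$params$condition_effects)
    }
    raw$params <- do.call(truth_params, raw$params)
  }
  if (!is.null(raw$n_per_condition)) {
    raw$n_per_condition <- unlist(raw$n_per_condition)
  }
  unknown <- setdiff(names(raw), names(formals(pipeline_config)))
  if (length(unknown)) {
    abort(sprintf("Unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  do.call(pipeline_config, raw)
}

#' Validate input CSVs for the pipeline
#'
#' Checks schema columns, the sampling-cadence grid, and date coverage
#' (every telemetry date present in the weather table). Returns diagnostics
#' rather than raising, so all problems surface at once.
#'
#' @param telemetry,ambient,weather Paths or already-read tibbles.
#' @param cadence_min Expected cadence in minutes.
#' @return A tibble `input`, `issue` (zero rows when everything checks out).
#' @export
validate_io <- function(telemetry, ambient = NULL, weather = NULL,
                        cadence_min = 10) {
  issues <- list()
  note <- function(input, issue) {
    issues[[length(issues) + 1L]] <<- tibble(input = input, issue = issue)
  }
  load_tbl <- function(x, reader, input) {
    if (is.character(x)) {
      if (!file.exists(x)) {
        note(input, sprintf("file not found: %s", x))
        return(NULL)
      }
      reader(x)
    } else {
      x
    }
  }

  tele <- load_tbl(telemetry, read_telemetry_csv, "telemetry")
  amb <- if (!is.null(ambient)) load_tbl(ambient, read_ambient_csv, "ambient")
  wx <- if (!is.null(weather)) load_tbl(weather, read_weather_csv, "weather")

  check_grid <- function(ts, input) {
    off <- (as.double(ts) %% (cadence_min * 60)) != 0
    if (any(off)) {
      note(input, sprintf(
        "%d timestamp(s) off the %d-min cadence grid (first: %s)",
        sum(off), cadence_min, format(ts[which(off)[1]], tz = "UTC")
      ))
    }
  }

  if (!is.null(tele)) {
    need <- c("individual_id", "timestamp", "t_sk")
    miss <- setdiff(need, names(tele))
    if (length(miss)) {
      note("telemetry", paste("missing column(s):", paste(miss, collapse = ", ")))
    } else {
      check_grid(tele$timestamp, "telemetry")
      dup <- tele |>
        count(.data$individual_id, .data$timestamp) |>
        filter(.data$n > 1)
      if (nrow(dup)) note("telemetry", sprintf("%d duplicated readings", nrow(dup)))
    }
  }
  if (!is.null(amb)) {
    if (!all(c("timestamp", "t_a") %in% names(amb))) {
      note("ambient", "missing column(s): needs timestamp, t_a")
    } else {
      check_grid(amb$timestamp, "ambient")
      if (is.unsorted(amb$timestamp, strictly = TRUE)) {
        note("ambient", "timestamps not strictly increasing")
      }
    }
  }
  if (!is.null(wx) && !is.null(tele) &&
    all(c("individual_id", "timestamp") %in% names(tele))) {
    if (!all(c("date", "max_wind_kmh", "precip_mm", "min_ta") %in% names(wx))) {
      note("weather", "missing column(s): needs date, max_wind_kmh, precip_mm, min_ta")
    } else {
      tele_dates <- unique(as.Date(tele$timestamp, tz = "UTC"))
      uncovered <- setdiff(as.character(tele_dates), as.character(wx$date))
      if (length(uncovered)) {
        note("weather", sprintf(
          "no weather for telemetry date(s): %s",
          paste(sort(uncovered), collapse = ", ")
        ))
      }
    }
  }
  if (length(issues)) list_rbind(issues) else tibble(input = character(), issue = character())
}

#' Run the full torpor analysis pipeline
#'
#' Executes simulate (or load) -> extract metrics -> fit every candidate
#' model -> rank by DIC -> variable weights -> model-averaged estimates, for
#' each requested response, writing the bat-day table, per-model fit
#' summaries, ranking/variable-weight/averaged-estimate CSVs, effect-curve
#' CSVs and a JSON run report into `config$outdir`. Every stage's RNG seed
#' derives from the master seed, so a rerun with the same config reproduces
#' the report exactly. Fits are cached on disk (keyed by model label, data
#' and MCMC settings), so a rerun pointed at the same `outdir` skips
#' already-fitted models.
#'
#' @param config A [pipeline_config()].
#' @return The run report (list), invisibly; also written as
#'   `report.json`.
#' @export
run_torpor_pipeline <- function(config) {
  stopifnot(inherits(config, "torpor_pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  quiet <- config$quiet
  report <- list(seed = config$seed, stages = character())
  run_stage <- function(name, expr) {
    report$stages <<- c(report$stages, name)
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage `%s` failed: %s", name, conditionMessage(e)))
    })
  }

  # --- input stage -----------------------------------------------------
  inputs <- run_stage("input", {
    if (config$synthetic) {
      p <- config$params
      env <- generate_environment(p$season_days, p)
      cohort <- generate_cohort(config$n_per_condition, p)
      sim <- simulate_telemetry(cohort, env, p)
      write_simulation_csv(sim, env, cohort, file.path(config$outdir, "data"))
      stage_log("input", "simulated %d individuals, %d readings",
        nrow(cohort), nrow(sim$telemetry),
        quiet = quiet
      )
      list(telemetry = sim$telemetry, weather = env$weather, occupancy = sim$occupancy)
    } else {
      issues <- validate_io(config$telemetry, config$ambient, config$weather,
        cadence_min = config$rules$cadence_min
      )
      if (nrow(issues)) {
        abort(paste(
          c("Input validation failed:", sprintf("- %s: %s", issues$input, issues$issue)),
          collapse = "\n"
        ))
      }
      stage_log("input", "loaded input CSVs", quiet = quiet)
      list(
        telemetry = read_telemetry_csv(config$telemetry),
        weather = read_weather_csv(config$weather),
        occupancy = NULL
      )
    }
  })

  # --- metrics stage ---------------------------------------------------
  daily <- run_stage("metrics", {
    r <- config$rules
    d <- extract_torpor_metrics(inputs$telemetry, inputs$occupancy,
      percentile = r$percentile, offset_c = r$offset_c, min_run = r$min_run,
      max_missing_min = r$max_missing_min, cadence_min = r$cadence_min,
      quiet = quiet
    )
    write_bat_days_csv(d, file.path(config$outdir, "bat_days.csv"))
    stage_log("metrics", "%d bat days retained (%d dropped), %d torpid",
      nrow(d), attr(d, "n_dropped") %||% 0L, sum(d$torpid),
      quiet = quiet
    )
    d
  })
  report$n_individuals <- dplyr::n_distinct(daily$individual_id)
  report$n_bat_days <- nrow(daily)
  report$n_dropped_days <- attr(daily, "n_dropped") %||% 0L
  report$torpid_fraction <- mean(daily$torpid)

  # --- fit / rank / average per response --------------------------------
  fit_dir <- file.path(config$outdir, "fits")
  dir.create(fit_dir, showWarnings = FALSE)
  report$responses <- list()

  for (resp in config$responses) {
    cands <- if (is.null(config$candidates)) {
      candidate_models(resp)$spec
    } else {
      map(config$candidates, ~ model_spec(resp, .x))
    }
    fits <- run_stage(paste0("fit_", resp), {
      purrr::imap(cands, function(spec, i) {
        md <- build_model_data(daily, inputs$weather, spec)
        key <- rlang::hash(list(
          spec$label, resp, md$y, md$X, md$cond_idx, md$ind_idx,
          config$mcmc, config$prior, config$seed
        ))
        cache <- file.path(fit_dir, paste0(key, ".rds"))
        if (file.exists(cache)) {
          fit <- readRDS(cache)
        } else {
          fit <- withCallingHandlers(
            sample_posterior(md,
              n_chains = config$mcmc$n_chains, n_iter = config$mcmc$n_iter,
              burn_in = config$mcmc$burn_in, thin = config$mcmc$thin,
              seed = child_seed(config$seed, 900L + 50L * match(resp, config$responses) + i),
              prior = prior_control(
                beta_sd = config$prior$beta_sd,
                sigma_scale = config$prior$sigma_scale
              )
            ),
            warning = function(w) {
              stage_log(paste0("fit_", resp), "%s: %s", spec$label,
                conditionMessage(w),
                quiet = quiet
              )
              invokeRestart("muffleWarning")
            }
          )
          saveRDS(fit, cache)
        }
        stage_log(paste0("fit_", resp), "%-45s DIC %8.2f (pD %5.2f)",
          spec$label, fit$dic, fit$p_d,
          quiet = quiet
        )
        fit
      })
    })

    res <- run_stage(paste0("rank_", resp), {
      readr::write_csv(
        list_rbind(map(fits, glance)),
        file.path(config$outdir, sprintf("fit_summaries_%s.csv", resp))
      )
      rank <- rank_models(fits, level = config$level)
      readr::write_csv(
        tidy(rank),
        file.path(config$outdir, sprintf("rank_%s.csv", resp))
      )
      vw <- variable_weights(confidence_set(rank), threshold = config$threshold)
      readr::write_csv(
        vw, file.path(config$outdir, sprintf("variable_weights_%s.csv", resp))
      )
      avg <- summarize_multimodel(rank,
        level = config$level, threshold = config$threshold
      )
      readr::write_csv(
        avg, file.path(config$outdir, sprintf("averaged_estimates_%s.csv", resp))
      )
      curves <- avg |>
        filter(.data$variable %in% c("wind", "precip", "min_ta")) |>
        group_by(.data$variable) |>
        group_modify(~ effect_curve(
          .x$beta0_avg[1], .x$estimate[1],
          family = if (resp == "frequency") "bernoulli" else "normal"
        )) |>
        ungroup()
      if (nrow(curves)) {
        readr::write_csv(
          curves, file.path(config$outdir, sprintf("effect_curves_%s.csv", resp))
        )
      }
      list(rank = rank, vw = vw, avg = avg)
    })

    report$responses[[resp]] <- list(
      top_model = res$rank$model[1],
      top_weight = res$rank$weight[1],
      conf_set_size = sum(res$rank$in_conf_set),
      max_rhat = max(map_dbl(fits, ~ max(.x$rhat, na.rm = TRUE))),
      converged = all(map_dbl(fits, ~ max(.x$rhat, na.rm = TRUE)) < 1.1),
      explanatory = res$vw$variable[res$vw$explanatory]
    )
  }

  report$config <- config_echo(config)
  jsonlite::write_json(report, file.path(config$outdir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
  stage_log("report", "written to %s", file.path(config$outdir, "report.json"),
    quiet = quiet
  )
  invisible(report)
}

# JSON-friendly echo of the configuration
config_echo <- function(config) {
  p <- unclass(config$params)
  p$condition_effects <- as.data.frame(p$condition_effects)
  list(
    synthetic = config$synthetic,
    telemetry = config$telemetry, ambient = config$ambient,
    weather = config$weather,
    n_per_condition = as.list(config$n_per_condition),
    rules = config$rules, responses = config$responses,
    candidates = config$candidates, mcmc = config$mcmc,
    prior = config$prior,
    level = config$level, threshold = config$threshold,
    seed = config$seed, params = p
  )
}
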