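#' Read and validate a run configuration
#'
#' A single YAML file drives a reproducible run. Keys:
#' * `actors`, `events`: input file paths ([read_actor_table()] /
#'   [read_event_list()] dialects); `output`: output directory;
#' * `seeds`: named integers `split`, `gof`, `simulate` — every stochastic
#'   step takes an explicit seed and a run without the seeds it needs fails
#'   fast;
#' * `likelihood` (`full`/`ordinal`), `calendar_start` (weekday name),
#'   `gof_share`, `traits` (columns to impute + standardize),
#'   `event_types` (typed risk set labels, optional);
#' * `window`: `length_days`, `step_days`, `min_events`;
#' * `models`: named list of effect-entry lists (each entry has `kind` plus
#'   parameters, see [effects()] and the vignette);
#' * `simulate`: simulator settings for [cmd_simulate()] (`preset: connect`
#'   or `n_actors`, `t_max_days`, `beta`, `effects`).
#'
#' @param path Path to the YAML file.
#' @param require_files Check that input files exist (default `TRUE`;
#'   `cmd_simulate()` does not need them).
#' @return A validated `rem_config` list.
#' @export
read_run_config <- function(path, require_files = TRUE) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path))
  }
  cfg <- yaml::read_yaml(path)
  cfg$likelihood <- cfg$likelihood %||% "full"
  cfg$calendar_start <- cfg$calendar_start %||% "Monday"
  cfg$gof_share <- cfg$gof_share %||% 0.05
  cfg$output <- cfg$output %||% "."
  if (require_files) {
    for (key in c("actors", "events")) {
      if (is.null(cfg[[key]])) {
        abort(paste0("config misses required path: ", key))
      }
      if (!file.exists(cfg[[key]])) {
        abort(paste0(key, " file not found: ", cfg[[key]]))
      }
    }
    if (is.null(cfg$seeds$split)) {
      abort("config misses seeds$split (group-splitting order seed)")
    }
  }
  if (!is.null(cfg$models)) {
    if (is.null(names(cfg$models)) || any(names(cfg$models) == "")) {
      abort("models must be a named list")
    }
  }
  structure(cfg, class = "rem_config")
}

config_models <- function(config) {
  if (is.null(config$models) || !length(config$models)) {
    abort("config defines no models")
  }
  lapply(config$models, function(entries) {
    effects(lapply(entries, effect_from_config))
  })
}

prepare_inputs <- function(config) {
  actors <- read_actor_table(config$actors)
  if (!is.null(config$traits)) {
    actors <- standardize_traits(actors, config$traits)
  } else {
    auto <- setdiff(
      names(actors)[vapply(actors, is.numeric, logical(1))], "age"
    )
    if (length(auto)) {
      actors <- standardize_traits(actors, auto)
    }
  }
  raw <- read_event_list(config$events, actors)
  split <- split_group_events(raw, seed = config$seeds$split)
  rs <- build_risk_set(actors, config$event_types)
  list(
    actors = actors, raw = raw, events = split$events,
    report = split$report, riskset = rs,
    calendar = rem_calendar(config$calendar_start)
  )
}

run_record <- function(config, extra, path) {
  rec <- c(
    list(
      package = "remdyn",
      version = as.character(utils::packageVersion("remdyn")),
      config_hash = rlang::hash(unclass(config)),
      config = unclass(config)
    ),
    extra
  )
  jsonlite::write_json(
    rec, path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
  invisible(path)
}

#' Fit the configured models to an event file
#'
#' Preprocess (read, impute + standardize, split groups), build one design
#' per configured model, fit each by maximum likelihood, and write per-model
#' coefficient tables (`fit_<model>.tsv`), a BIC/gof comparison table
#' (`bic_table.tsv`) and a machine-readable run record
#' (`run_record_fit.json`) into the output directory.
#'
#' @param config A [read_run_config()] result.
#' @return Invisibly, a list with the fits, the gof values and the
#'   preprocessing report.
#' @export
cmd_fit <- function(config) {
  inp <- prepare_inputs(config)
  models <- config_models(config)
  dir.create(config$output, showWarnings = FALSE, recursive = TRUE)
  fits <- list()
  gofs <- list()
  rows <- list()
  for (nm in names(models)) {
    message("fitting model '", nm, "' (", length(models[[nm]]), " effects)")
    design <- build_design(
      inp$events, inp$riskset, inp$actors, models[[nm]],
      calendar = inp$calendar
    )
    fit <- fit_rem(design, kind = config$likelihood)
    gof <- NA_real_
    if (!is.null(config$seeds$gof)) {
      gof <- top_share_hit_rate(
        fit$coefficients, design,
        share = config$gof_share, seed = config$seeds$gof
      )$hit_rate
    }
    write_fit_summary(fit, file.path(config$output, paste0("fit_", nm, ".tsv")))
    fits[[nm]] <- fit
    gofs[[nm]] <- gof
    rows[[nm]] <- tibble::tibble(
      model = nm, npar = fit$P, n_events = fit$M,
      logLik = fit$loglik, BIC = fit$bic, gof = gof
    )
  }
  bic_tab <- dplyr::bind_rows(rows)
  readr::write_tsv(bic_tab, file.path(config$output, "bic_table.tsv"))
  run_record(
    config,
    list(
      preprocess = as.list(inp$report),
      models = lapply(names(fits), function(nm) {
        list(
          model = nm,
          coefficients = as.list(fits[[nm]]$coefficients),
          se = as.list(fits[[nm]]$se),
          logLik = fits[[nm]]$loglik, BIC = fits[[nm]]$bic,
          gof = gofs[[nm]]
        )
      })
    ),
    file.path(config$output, "run_record_fit.json")
  )
  invisible(list(fits = fits, gof = gofs, report = inp$report, bic = bic_tab))
}

#' Fit the configured models in moving windows
#'
#' Runs the moving-window procedure for each configured model and writes a
#' long-format trajectory file per model (`trajectory_<model>.tsv`) plus a
#' run record.
#'
#' @param config A [read_run_config()] result with a `window` section.
#' @return Invisibly, the list of `rem_window_trajectory` objects.
#' @export
cmd_fit_windows <- function(config) {
  if (is.null(config$window)) {
    abort("config misses the window section")
  }
  inp <- prepare_inputs(config)
  models <- config_models(config)
  dir.create(config$output, showWarnings = FALSE, recursive = TRUE)
  span_end <- ceiling(max(inp$events$stat_time) / 1440) * 1440
  windows <- make_windows(
    0, span_end,
    length_minutes = config$window$length_days * 1440,
    step_minutes = config$window$step_days * 1440
  )
  out <- list()
  for (nm in names(models)) {
    message("moving-window fit for model '", nm, "'")
    traj <- fit_moving_window(
      inp$events, inp$riskset, inp$actors, models[[nm]],
      windows = windows, kind = config$likelihood,
      calendar = inp$calendar,
      min_events = config$window$min_events %||% 100,
      gof_share = config$gof_share, gof_seed = config$seeds$gof
    )
    write_trajectory(
      traj, file.path(config$output, paste0("trajectory_", nm, ".tsv"))
    )
    out[[nm]] <- traj
  }
  run_record(
    config,
    list(windows = lapply(out, function(tr) as.list(tr$windows))),
    file.path(config$output, "run_record_windows.json")
  )
  invisible(out)
}

#' Simulate an event history and write it in the input dialects
#'
#' With `simulate: {preset: connect}` the synthetic freshman-network
#' generator is used; otherwise a basic custom configuration (`n_actors`,
#' `t_max_days`, `effects`, `beta`) is honoured. Writes `actors.csv`,
#' `events.csv` and a truth record (`run_record_simulate.json`, containing
#' the exact coefficients and seed) into the output directory.
#'
#' @param config A [read_run_config()] result with a `simulate` section and
#'   `seeds$simulate`.
#' @return Invisibly, the simulation result.
#' @export
cmd_simulate <- function(config) {
  sim_cfg <- config$simulate
  if (is.null(sim_cfg)) {
    abort("config misses the simulate section")
  }
  if (is.null(config$seeds$simulate)) {
    abort("config misses seeds$simulate")
  }
  seed <- config$seeds$simulate
  if (identical(sim_cfg$preset, "connect")) {
    sim <- generate_connect_like(seed)
  } else {
    n <- sim_cfg$n_actors %||% abort("simulate needs n_actors or a preset")
    actors <- withr::with_seed(seed, tibble::tibble(
      actor_id = sprintf("a%03d", seq_len(n)),
      gender = sample(
        c("female", "male"), n, TRUE,
        prob = c(sim_cfg$prop_female %||% 0.5, 1 - (sim_cfg$prop_female %||% 0.5))
      ),
      age = sample(18:30, n, TRUE),
      trait = rnorm(n)
    ))
    actors$age_group <- ifelse(actors$age <= 24, "young", "older")
    actors <- standardize_traits(actors, "trait")
    specs <- effects(lapply(sim_cfg$effects, effect_from_config))
    sim <- simulate_rem(sim_config(
      actors = actors, specs = specs,
      beta = unlist(sim_cfg$beta),
      t_max = (sim_cfg$t_max_days %||% 23) * 1440,
      seed = seed + 1L,
      calendar = rem_calendar(config$calendar_start)
    ))
    sim$events$time <- pmax(1, round(sim$events$time))
  }
  dir.create(config$output, showWarnings = FALSE, recursive = TRUE)
  write_actor_table(sim$actors, file.path(config$output, "actors.csv"))
  write_event_list(sim$events, file.path(config$output, "events.csv"))
  run_record(
    config,
    list(truth = list(
      beta = as.list(sim$truth$beta), seed = sim$truth$seed,
      n_events = nrow(sim$events),
      riskset_size = nrow(build_risk_set(sim$actors))
    )),
    file.path(config$output, "run_record_simulate.json")
  )
  invisible(sim)
}

#' Dump the observed-event statistics of a configured model
#'
#' Diagnostic export: for each observed dyadic event, the statistic values
#' of its own risk-set entry under the first (or named) configured model.
#'
#' @param config A [read_run_config()] result.
#' @param model Model name; default the first configured model.
#' @param max_events Cap on exported rows.
#' @return Invisibly, the exported tibble (also written to
#'   `stats_<model>.tsv` in the output directory).
#' @export
cmd_stats <- function(config, model = NULL, max_events = 5000) {
  inp <- prepare_inputs(config)
  models <- config_models(config)
  model <- model %||% names(models)[1]
  if (!model %in% names(models)) {
    abort(paste0("unknown model: ", model))
  }
  design <- build_design(
    inp$events, inp$riskset, inp$actors, models[[model]],
    calendar = inp$calendar
  )
  keep <- seq_len(min(design$M, max_events))
  obs_lin <- (keep - 1) * design$R + design$obs[keep]
  out <- dplyr::bind_cols(
    design$events[keep, c("group_id", "time", "stat_time", "actor1", "actor2")],
    tibble::as_tibble(design$X[obs_lin, , drop = FALSE])
  )
  dir.create(config$output, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(out, file.path(config$output, paste0("stats_", model, ".tsv")))
  invisible(out)
}
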