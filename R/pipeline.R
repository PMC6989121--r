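# End-to-end orchestration: one structured config (YAML file or nested
# list) drives simulate/load -> event detection -> SP detection -> behavior
# -> stimulus response -> graph export, and produces a machine-readable run
# report echoing every parameter. Identical config + seed gives a
# byte-identical report.

run_config_schema <- function() list(
  top = c("seed", "stages", "simulate", "inputs", "events", "sp",
          "behavior", "stim"),
  simulate = names(formals(synth_config)),
  inputs = c("traces", "region_map", "accel", "stim"),
  events = c("rise_tau_s", "t_half_s", "threshold", "refractory_s",
             "noise_estimator"),
  sp = c("h_s", "dt_s", "min_co", "n_sigma", "robust"),
  behavior = c("win_s", "around_s", "baseline_frac", "lp_cutoff_hz",
               "n_random_triggers", "rearing", "turns"),
  stim = c("pre_s", "post_s", "align", "alpha", "response_window")
)

check_keys <- function(block, allowed, where) {
  bad <- setdiff(names(block), allowed)
  if (length(bad) > 0L) {
    abort(sprintf("unknown config key(s) in %s: %s", where,
                  paste(bad, collapse = ", ")))
  }
}

#' Validate a pipeline run configuration
#'
#' A run config is a nested list (or YAML file) with a `seed`, the `stages`
#' to run (any of `"events"`, `"sp"`, `"behavior"`, `"stim"`), exactly one
#' of `simulate` (overrides for [synth_config()]) or `inputs` (paths to
#' `traces` + `region_map`, optionally `accel` and `stim` CSVs), and optional
#' per-stage parameter blocks (`events`, `sp`, `behavior`, `stim`). Unknown
#' keys anywhere are rejected before any computation.
#'
#' @param config nested list or path to a YAML file.
#' @return The validated config list, invisibly classed `run_config`.
#' @export
validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("config must be a list or a YAML file path")
  schema <- run_config_schema()
  check_keys(config, schema$top, "top level")
  if (is.null(config$seed)) abort("config needs a seed")
  if (is.null(config$stages)) {
    config$stages <- c("events", "sp", "behavior", "stim")
    # a simulated session without stimulation has nothing for the stim
    # stage; only run it by default when trials will exist
    n_stim <- config$simulate$n_stim %||% 0L
    if (!is.null(config$simulate) && n_stim == 0L) {
      config$stages <- setdiff(config$stages, "stim")
    }
  }
  bad <- setdiff(config$stages, c("events", "sp", "behavior", "stim"))
  if (length(bad) > 0L) {
    abort(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  }
  has_sim <- !is.null(config$simulate)
  has_inp <- !is.null(config$inputs)
  if (has_sim == has_inp) {
    abort("config needs exactly one of 'simulate' or 'inputs'")
  }
  for (blk in c("simulate", "inputs", "events", "sp", "behavior", "stim")) {
    if (!is.null(config[[blk]])) {
      check_keys(config[[blk]], schema[[blk]], blk)
    }
  }
  if (has_inp) {
    if (is.null(config$inputs$traces) || is.null(config$inputs$region_map)) {
      abort("inputs must name 'traces' and 'region_map' files")
    }
    if ("behavior" %in% config$stages && is.null(config$inputs$accel)) {
      abort("behavior stage enabled but inputs has no 'accel' path")
    }
    if ("stim" %in% config$stages && is.null(config$inputs$stim)) {
      abort("stim stage enabled but inputs has no 'stim' path")
    }
  }
  structure(config, class = c("run_config", "list"))
}

run_stage <- function(name, log_con, expr) {
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(force(expr), error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
  if (!is.null(log_con)) {
    writeLines(sprintf("stage %-10s %8.2f s", name,
                       proc.time()[["elapsed"]] - t0), log_con)
  }
  out
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages and writes all artifacts plus a
#' `report.json` to `out_dir`. The report echoes the full configuration and
#' contains every stage's headline quantities (per-region event rates and
#' half-decay medians, sync-event and SP counts, scope participation,
#' SP-trigger category fractions, rearing/turn statistics, responder
#' fraction, modulation cluster fractions). A `pipeline.log` records stage
#' timings and is the only output that differs between identical runs.
#'
#' @param config a [validate_run_config()]-acceptable config.
#' @param out_dir output directory, created if needed.
#' @return The report, invisibly (also written as JSON).
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_con <- file(file.path(out_dir, "pipeline.log"), open = "wt")
  on.exit(close(log_con), add = TRUE)
  report <- list(seed = cfg$seed, stages = cfg$stages,
                 config = unclass(cfg), outputs = list())
  manifest <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    readr::write_csv(df, path, progress = FALSE)
    manifest <<- c(manifest, name)
  }

  # --- input stage ------------------------------------------------------
  session <- run_stage("input", log_con, {
    if (!is.null(cfg$simulate)) {
      sim_args <- cfg$simulate
      sim_args$seed <- sim_args$seed %||% cfg$seed
      simulate_session(do.call(synth_config, sim_args))
    } else {
      rm_df <- readr::read_csv(cfg$inputs$region_map, show_col_types = FALSE,
                               progress = FALSE)
      list(
        traces = read_trace_table(cfg$inputs$traces, rm_df),
        accel = if (!is.null(cfg$inputs$accel)) {
          read_accel_table(cfg$inputs$accel)
        },
        stim = if (!is.null(cfg$inputs$stim)) {
          read_stim_table(cfg$inputs$stim)
        },
        truth = NULL
      )
    }
  })
  tm <- session$traces
  duration_s <- max(tm$t) + 1 / tm$frame_rate_hz
  report$outputs$input <- list(
    n_cells = nrow(tm$values),
    n_frames = ncol(tm$values),
    duration_s = duration_s,
    regions = as.list(table(tm$cells$region))
  )

  events <- NULL
  if ("events" %in% cfg$stages) {
    events <- run_stage("events", log_con, {
      detect_events(tm, do.call(onset_params, cfg$events %||% list()))
    })
    emit(events, "events.csv")
    rates <- event_rate(events, duration_s, cell_ids = tm$cells)
    hd <- half_decay_summary(tm, events)
    emit(rates, "event_rates.csv")
    by_region <- dplyr::summarise(dplyr::group_by(rates, .data$region),
                                  mean_rate_hz = mean(.data$rate_hz),
                                  .groups = "drop")
    report$outputs$events <- list(
      n_events = nrow(events),
      mean_rate_hz = setNames(as.list(by_region$mean_rate_hz),
                              by_region$region),
      median_t_half_s = setNames(as.list(hd$summary$median_t_half_s),
                                 hd$summary$region)
    )
  }

  if ("sp" %in% cfg$stages) {
    sp <- run_stage("sp", log_con, {
      if (is.null(events) || nrow(events) == 0L) {
        abort("sp stage needs detected events")
      }
      args <- cfg$sp %||% list()
      do.call(detect_sp, c(list(events = events, cells = tm$cells,
                                duration_s = duration_s), args))
    })
    emit(tidy(sp$kernel_sum), "kernel_sum.csv")
    emit(sp$sync_events[c("event_id", "t0", "t1", "n_participants")],
         "sync_events.csv")
    emit(sp$scope$edges, "sp_edges.csv")
    export_graph(sp$graph, file.path(out_dir, "sp_graph.graphml"),
                 format = "graphml")
    manifest <- c(manifest, "sp_graph.graphml")
    layout <- degree_layout(sp$graph)
    emit(as_tibble(layout), "arc_layout.csv")
    report$outputs$sp <- c(
      as.list(glance(sp$graph)),
      list(participation = lapply(
        split(sp$scope$participation, sp$scope$participation$region),
        function(r) list(frac_within = r$frac_within,
                         frac_across = r$frac_across)
      ))
    )
    sp_times <- (sp$sync_events$t0 + sp$sync_events$t1) / 2
  } else {
    sp_times <- numeric(0)
  }

  if ("behavior" %in% cfg$stages) {
    beh <- run_stage("behavior", log_con, {
      if (is.null(session$accel)) abort("behavior stage needs an IMU record")
      bcfg <- cfg$behavior %||% list()
      acc <- session$accel
      a <- compound_accel(acc)
      trig_args <- bcfg[intersect(names(bcfg),
                                  c("win_s", "around_s", "baseline_frac",
                                    "lp_cutoff_hz"))]
      trig <- do.call(classify_sp_triggers,
                      c(list(a = a, sp_times = sp_times), trig_args))
      null <- if (length(sp_times) > 0L) {
        do.call(random_trigger_null,
                c(list(a = a, sp_times = sp_times,
                       n_triggers = bcfg$n_random_triggers %||% 100L,
                       seed = cfg$seed), trig_args))
      }
      rear <- do.call(detect_rearings,
                      c(list(acc = acc), bcfg$rearing %||% list()))
      turns <- do.call(detect_turns,
                       c(list(acc = acc), bcfg$turns %||% list()))
      list(a = a, trig = trig, null = null, rear = rear, turns = turns)
    })
    emit(beh$trig$classes, "sp_trigger_classes.csv")
    emit(dplyr::bind_rows(beh$rear$epochs, beh$turns), "behavior_epochs.csv")
    report$outputs$behavior <- list(
      trigger_fractions = setNames(as.list(beh$trig$fractions$fraction),
                                   beh$trig$fractions$category),
      n_sp_classified = nrow(beh$trig$classes),
      n_sp_dropped_edge = beh$trig$n_dropped_edge,
      random_trigger = if (!is.null(beh$null)) as.list(beh$null),
      rearing = as.list(beh$rear$stats),
      n_turns = nrow(beh$turns)
    )
  }

  if ("stim" %in% cfg$stages) {
    st <- run_stage("stim", log_con, {
      if (is.null(session$stim)) abort("stim stage needs a stimulation log")
      scfg <- cfg$stim %||% list()
      tt <- build_trials(tm, session$stim,
                         pre_s = scfg$pre_s %||% 2,
                         post_s = scfg$post_s %||% 3,
                         align = scfg$align %||% "onset")
      resp <- classify_responders(tt, response_window = scfg$response_window)
      mod <- classify_modulation(tt, events = events,
                                 alpha = scfg$alpha %||% 0.05)
      list(tt = tt, resp = resp, mod = mod)
    })
    emit(st$resp$calls, "responders.csv")
    emit(st$mod$calls, "modulation.csv")
    report$outputs$stim <- list(
      n_trials = dim(st$tt$data)[2],
      n_trials_dropped = st$tt$n_dropped,
      responder_fraction = st$resp$responder_fraction,
      modulation_fractions = setNames(as.list(st$mod$fractions$fraction),
                                      st$mod$fractions$class),
      cluster_rates_hz = setNames(as.list(st$mod$fractions$mean_rate_hz),
                                  st$mod$fractions$class)
    )
  }

  report$manifest <- sort(c(manifest, "report.json"))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       null = "null")
  invisible(report)
}
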