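#' Run the full analysis pipeline into a run directory
#'
#' Chains simulate -> normalize -> detect -> network -> metrics on a
#' scenario configuration and writes every export plus a machine-readable
#' run manifest. The run is a pure function of the configuration (which
#' includes the seed): re-running with the same config produces
#' byte-identical outputs.
#'
#' Files written: \code{traces.csv} (+ \code{traces.csv.json} sidecar),
#' \code{ground_truth.csv}, \code{events.csv}, \code{activity.json},
#' \code{graph.graphml}, \code{edges.csv}, \code{metrics.json},
#' \code{metrics.csv}, \code{distance_correlation.csv},
#' \code{recovery.json}, \code{manifest.json}.
#'
#' @param config a [scenario()], a named list of scenario arguments, or a
#'   path to a JSON/YAML scenario file. An optional \code{condition} key
#'   ("sham" or "hypoxia") selects a preset.
#' @param out_dir run directory (created; must be empty or absent unless
#'   \code{overwrite}).
#' @param overwrite allow writing into an existing directory.
#' @param verbose print one log line per stage.
#' @return invisibly, a list with the in-memory results
#'   (\code{traces}, \code{activity}, \code{graph}, \code{metrics},
#'   \code{recovery}, \code{out_dir}).
#' @export
run_pipeline <- function(config, out_dir, overwrite = FALSE,
                         verbose = TRUE) {
  say <- function(...) if (verbose) message("[calcinet] ", sprintf(...))
  scn <- as_scenario(config)
  if (dir.exists(out_dir) && length(dir(out_dir)) && !overwrite)
    stop("output directory exists and is not empty: ", out_dir,
         call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)

  say("simulate: %d cells, %gs at %g Hz, seed %d", scn$n_cells,
      scn$duration, scn$sampling_rate, scn$seed)
  rec <- simulate_recording(scn)
  write_trace_table(rec$traces, p("traces.csv"))
  write_ground_truth(rec$ground_truth$edges, p("ground_truth.csv"))

  say("activity: dF/F + oscillation detection")
  dff <- compute_dff(rec$traces)
  events <- detect_oscillations(dff)
  utils::write.csv(events, p("events.csv"), row.names = FALSE)
  act <- summarize_activity(events, dff)
  jsonlite::write_json(
    list(percent_active = act$percent_active,
         mean_duration_s = act$mean_duration,
         mean_frequency_osc_min = act$mean_frequency,
         n_cells = act$n_cells,
         recording_duration_s = act$recording_duration),
    p("activity.json"), auto_unbox = TRUE, digits = NA, na = "null",
    pretty = TRUE)

  say("network: lagged-correlation graph (rho > 0.3)")
  graph <- build_graph(dff)
  export_graph(graph, graphml = p("graph.graphml"), csv = p("edges.csv"))
  metrics <- compute_metrics(graph)
  export_metrics(metrics, json = p("metrics.json"), csv = p("metrics.csv"))
  dc <- correlation_vs_distance(graph)
  utils::write.csv(dc$points, p("distance_correlation.csv"),
                   row.names = FALSE)

  say("validation: recovery vs planted ground truth")
  recov <- evaluate_recovery(graph, rec$ground_truth)
  jsonlite::write_json(recov, p("recovery.json"), auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)

  cfg_path <- p("scenario.json")
  jsonlite::write_json(scn[setdiff(names(scn), "effective")], cfg_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  outputs <- setdiff(dir(out_dir), "manifest.json")
  manifest <- list(
    package = "calcinet",
    version = as.character(utils::packageVersion("calcinet")),
    seed = scn$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    outputs = as.list(tools::md5sum(file.path(out_dir, sort(outputs))))
  )
  names(manifest$outputs) <- sort(outputs)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  say("done: %s", out_dir)
  invisible(list(traces = rec$traces, ground_truth = rec$ground_truth,
                 activity = act, graph = graph, metrics = metrics,
                 recovery = recov, out_dir = out_dir))
}

as_scenario <- function(config) {
  if (inherits(config, "ca_scenario")) return(validate_scenario(config))
  if (is.character(config) && length(config) == 1)
    return(read_scenario(config))
  if (is.list(config)) {
    condition <- config$condition
    config$condition <- NULL
    if (!is.null(config$condition_scaling))
      config$condition_scaling <- unlist(config$condition_scaling)
    ctor <- switch(condition %||% "none",
                   sham = sham_scenario,
                   hypoxia = hypoxia_scenario,
                   none = scenario,
                   stop("unknown condition preset: ", condition,
                        call. = FALSE))
    return(do.call(ctor, config))
  }
  stop("config must be a scenario, a named list or a file path",
       call. = FALSE)
}

#' Batch-compare sham and hypoxia conditions over paired seeds
#'
#' Runs the full pipeline in memory for both condition presets over a set
#' of seeds and compares every activity and network metric between the two
#' groups with [compare_groups()].
#'
#' @param seeds integer vector of master seeds (>= 3 for the tests to run).
#' @param ... scenario overrides common to both conditions.
#' @param test passed to [compare_groups()].
#' @return list with \code{samples} (data.frame: condition, seed, one
#'   column per metric) and \code{comparisons} (named list of
#'   \code{"ca_group_comparison"} objects).
#' @export
compare_conditions <- function(seeds, ..., test = "mann-whitney") {
  rows <- list()
  for (cond in c("sham", "hypoxia")) {
    ctor <- if (cond == "sham") sham_scenario else hypoxia_scenario
    for (s in seeds) {
      res <- analyze_scenario(ctor(..., seed = s))
      rows[[length(rows) + 1]] <- cbind(
        data.frame(condition = cond, seed = s, stringsAsFactors = FALSE),
        as.data.frame(as.list(res)))
    }
  }
  samples <- do.call(rbind, rows)
  metric_cols <- setdiff(names(samples), c("condition", "seed"))
  comparisons <- lapply(metric_cols, function(m) {
    by_g <- split(samples[[m]], samples$condition)
    by_g <- lapply(by_g, function(v) v[is.finite(v)])
    if (any(lengths(by_g) < 3)) return(NULL)
    compare_groups(by_g, test = test, metric = m)
  })
  names(comparisons) <- metric_cols
  list(samples = samples,
       comparisons = comparisons[!vapply(comparisons, is.null,
                                         logical(1))])
}

# one scenario -> flat named vector of activity + network metrics
analyze_scenario <- function(scn) {
  rec <- simulate_recording(scn)
  dff <- compute_dff(rec$traces)
  act <- summarize_activity(detect_oscillations(dff), dff)
  metrics <- compute_metrics(build_graph(dff))
  c(percent_active = act$percent_active,
    mean_duration = act$mean_duration,
    mean_frequency = act$mean_frequency,
    mean_corr_all = metrics$mean_corr_all,
    mean_corr_adjacent = metrics$mean_corr_adjacent,
    mean_connections_per_cell = metrics$mean_connections_per_cell,
    percent_possible_connections = metrics$percent_possible_connections,
    mean_delay_rate = metrics$mean_delay_rate)
}
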