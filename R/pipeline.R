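## Reproducible pipeline runner: composes the package stages from a config
## (R list or YAML/JSON file), writes tidy CSV/JSON artifacts plus a
## manifest with the configuration, seeds and package version.

#' Run a composition of analysis stages
#'
#' Executes the stages named in `config$stages` and writes each stage's
#' artifacts into `out_dir`.  Supported stages:
#' * `derive` — derived-parameter table of a module preset
#'   (`derived.json`);
#' * `simulate` — trajectory under a protocol (`timeseries.csv` + JSON
#'   sidecar);
#' * `analyze` — spike detection and features on the simulated (or a
#'   user-supplied) trace (`spikes.csv`, `features.json`);
#' * `synth` — fluorescence emulation of the simulated trajectory
#'   (`fluorescence.csv`);
#' * `bifurcate` — attractor sweep over a cGMP grid (`attractors.csv`);
#' * `explore` — a budgeted evolutionary exploration
#'   (`population.jsonl`, `clusters.csv`).
#'
#' Configuration fields (all optional, with defaults): `module`, `S0`,
#' `end_time`, `dt`, `seed`, `G_grid`, `g_bk_scale`, `budget_neutral`,
#' `budget_selective`, `theta_values`, `noise_sd`, `scale`, `events`
#' (list of `list(kind=, ...)` event specs).  Two invocations with the same
#' configuration and seed produce identical artifacts.
#'
#' @param config an R list, or path to a YAML/JSON file with these fields.
#' @param out_dir output directory (created if missing).
#' @return the output directory path, invisibly; a `manifest.json` listing
#'   stages, seeds and timings is always written.
#' @export
run_pipeline <- function(config, out_dir = tempfile("flagspike_run_")) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE))
      yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages %||% c("derive", "simulate", "analyze")
  module <- config$module %||% "cav_bk"
  seed <- config$seed %||% 1
  timings <- list()
  ts <- NULL

  build_proto <- function() {
    evs <- config$events
    if (is.null(evs))
      evs <- list(list(kind = "sap_pulse", time = 0, S0 = config$S0 %||% 25))
    ev_objs <- lapply(evs, function(e) switch(e$kind,
      sap_pulse = ev_sap_pulse(e$time %||% 0, e$S0 %||% 25),
      clamp_ph = ev_clamp_ph(e$time, e$pH_target),
      voltage_pulse = ev_voltage_pulse(e$time, e$V_clamp, e$duration),
      stop("unknown event kind: ", e$kind)))
    do.call(protocol, c(ev_objs,
                        list(t_start = config$t_start %||% -2,
                             end_time = config$end_time %||% 25,
                             dt = config$dt %||% 0.005)))
  }

  for (st in stages) {
    t0 <- proc.time()[["elapsed"]]
    if (st == "derive") {
      tab <- derived_table(module)
      jsonlite::write_json(lapply(tab, as.list),
                           file.path(out_dir, "derived.json"),
                           auto_unbox = TRUE, digits = NA)
    } else if (st == "simulate") {
      ts <- simulate_model(reference_params(module), module_config(module),
                           build_proto())
      write_timeseries(ts, file.path(out_dir, "timeseries.csv"))
    } else if (st == "analyze") {
      src <- if (!is.null(config$trace_file)) read_trace(config$trace_file)
             else ts
      if (is.null(src)) stop("analyze stage needs a simulate stage or a ",
                             "trace_file")
      tr <- detect_spikes(src, stimulus_time = config$stimulus_time %||% 0,
                          value_col = if (!is.null(config$trace_file))
                            "value" else NULL)
      utils::write.csv(tr$spikes, file.path(out_dir, "spikes.csv"),
                       row.names = FALSE)
      ft <- spike_features(tr)
      sel <- meets_selection_criteria(ft,
        resting_C = config$resting_C %||% 100)
      jsonlite::write_json(
        c(as.list(ft), list(selected = as.logical(sel),
                            threshold = tr$threshold)),
        file.path(out_dir, "features.json"), auto_unbox = TRUE, digits = NA)
    } else if (st == "synth") {
      if (is.null(ts)) stop("synth stage needs a simulate stage")
      fl <- make_fluorescence(ts, scale = config$scale %||% 1,
                              noise_sd = config$noise_sd %||% 20,
                              seed = seed)
      utils::write.csv(fl, file.path(out_dir, "fluorescence.csv"),
                       row.names = FALSE)
    } else if (st == "bifurcate") {
      tab <- attractor_sweep(reference_params(module), module,
                             G_grid = config$G_grid %||% c(5, 10, 20),
                             g_bk_scale = config$g_bk_scale %||% 1,
                             n_init = config$n_init %||% 8,
                             t_transient = config$t_transient %||% 100,
                             seed = seed)
      utils::write.csv(tab, file.path(out_dir, "attractors.csv"),
                       row.names = FALSE)
    } else if (st == "explore") {
      thetas <- config$theta_values %||% c(1e-4, 1)
      pop <- evolve_population(seed_grid(thetas),
                               budget_neutral = config$budget_neutral %||% 5,
                               budget_selective =
                                 config$budget_selective %||% 5,
                               seed = seed)
      pop <- cluster_population(pop)
      write_population(pop, file.path(out_dir, "population.jsonl"))
      utils::write.csv(attr(pop, "cluster_summary"),
                       file.path(out_dir, "clusters.csv"),
                       row.names = FALSE)
    } else stop("unknown pipeline stage: ", st)
    timings[[st]] <- round(proc.time()[["elapsed"]] - t0, 3)
  }

  manifest <- list(stages = stages, module = module, seed = seed,
                   config = config, timings = timings,
                   package_version =
                     as.character(utils::packageVersion("flagspike")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
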