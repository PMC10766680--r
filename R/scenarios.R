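#' Build the factorial experiment set
#'
#' The default suite holds 23 runs: the climate-driven reference with fire,
#' the reference without fire, six one-at-a-time sensitivity runs (monthly
#' temperature, monthly precipitation, and fire-induced mortality each at
#' 0.95 and 1.05), and the 15 fixed-scenario runs crossing fire intensity
#' (0.1, 0.5, 1.0) with fire return interval (10, 50, 100, 200, 300 years),
#' in which every fire affects the whole simulation area at exactly the
#' labeled intensity.
#'
#' @param base an [run_config()] shared by all runs (its fire mode and
#'   perturbations are overridden per scenario).
#' @param fri_levels,fi_levels scenario grid levels.
#' @return named list of `fl_config` objects.
#' @export
scenario_configs <- function(base = run_config(),
                             fri_levels = c(10, 50, 100, 200, 300),
                             fi_levels = c(0.1, 0.5, 1.0)) {
  reset <- function(cfg) {
    cfg$fire_mode <- "climate_driven"
    cfg$fixed_fri <- NULL; cfg$fixed_fi <- NULL
    cfg$perturb_t <- 1; cfg$perturb_p <- 1; cfg$perturb_mortality <- 1
    cfg
  }
  out <- list()
  out$fire <- reset(base)
  nofire <- reset(base); nofire$fire_mode <- "off"
  out$no_fire <- nofire
  for (var in c("t", "p", "mortality")) {
    for (f in c(0.95, 1.05)) {
      cfg <- reset(base)
      cfg[[paste0("perturb_", var)]] <- f
      out[[sprintf("sens_%s_%s", var, ifelse(f > 1, "plus", "minus"))]] <-
        cfg
    }
  }
  for (fi in fi_levels) {
    for (fri in fri_levels) {
      cfg <- reset(base)
      cfg$fire_mode <- "fixed"
      cfg$fixed_fri <- fri
      cfg$fixed_fi <- fi
      out[[sprintf("fixed_fri%d_fi%g", fri, fi)]] <- cfg
    }
  }
  out
}

#' Run the experiment suite
#'
#' Executes (or just materializes) the scenario set of [scenario_configs()]
#' against one landscape and climate series. Each run gets its own
#' subdirectory with `manifest.yaml` (the fully resolved configuration and
#' seed) and, when executed, `annual.csv`, `fires.csv`, and snapshot
#' rasters.
#'
#' @param landscape an `fl_landscape`.
#' @param climate an `fl_climate`.
#' @param out_dir output directory (one subdirectory per run).
#' @param traits species trait table.
#' @param base an [run_config()] shared by all runs.
#' @param scenarios optional pre-built list from [scenario_configs()].
#' @param execute run the simulations (`FALSE` writes manifests only).
#' @param overwrite allow writing into an existing run directory.
#' @param progress per-century progress messages.
#' @return named list of run directories (invisibly the results when
#'   `execute`).
#' @export
run_experiment_suite <- function(landscape, climate, out_dir,
                                 traits = species_defaults(),
                                 base = run_config(), scenarios = NULL,
                                 execute = TRUE, overwrite = FALSE,
                                 progress = FALSE) {
  scenarios <- scenarios %||% scenario_configs(base)
  results <- list()
  for (nm in names(scenarios)) {
    dir <- file.path(out_dir, nm)
    if (dir.exists(dir) && !overwrite)
      stop_fl("output directory %s exists (use overwrite = TRUE)", dir)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    cfg <- scenarios[[nm]]
    yaml::write_yaml(config_manifest(cfg, list(scenario = nm)),
                     file.path(dir, "manifest.yaml"))
    if (execute) {
      sim <- fl_simulation(landscape, climate, traits, cfg)
      fl_run(sim, progress = progress)
      res <- simulation_results(sim)
      write_run_outputs(res, dir, landscape)
      results[[nm]] <- res
    }
  }
  invisible(if (execute) results else scenarios)
}

#' Write run outputs to a directory
#'
#' `annual.csv` (the annual record schema), `fires.csv` (fire log with
#' impact tallies), and per-layer ESRI ASCII snapshot rasters
#' (`snapshot_<year>_<layer>.asc`).
#'
#' @param res a [simulation_results()] list.
#' @param dir output directory.
#' @param landscape the run's `fl_landscape` (for raster georeferencing).
#' @export
write_run_outputs <- function(res, dir, landscape = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(res$annual, file.path(dir, "annual.csv"), row.names = FALSE,
            quote = FALSE)
  write.csv(res$fires, file.path(dir, "fires.csv"), row.names = FALSE,
            quote = FALSE)
  cellsize <- if (!is.null(landscape)) landscape$coarse_res else 90
  for (snap in res$snapshots) {
    for (layer in c("litter", "active_layer")) {
      write_esri_ascii(snap[[layer]],
                       file.path(dir, sprintf("snapshot_%d_%s.asc",
                                              snap$year, layer)),
                       cellsize = cellsize)
    }
  }
  invisible(dir)
}
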