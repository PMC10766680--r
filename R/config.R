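#' Run configuration
#'
#' Assembles and validates the configuration of a simulation run. Fire can
#' be `climate_driven` (ignitions drawn from the calibrated annual rating),
#' `off`, or `fixed` (whole-area fires at intensity `fixed_fi` every
#' `fixed_fri` years, after any spin-up; this is the scenario mode of the
#' fixed fire-return-interval by fire-intensity experiments). One-at-a-time
#' sensitivity runs perturb monthly temperature, precipitation, or
#' fire-induced mortality by a factor (0.95, 1, or 1.05).
#'
#' @param fire_mode one of `"climate_driven"`, `"off"`, `"fixed"`.
#' @param fixed_fri fire return interval, yr (required in fixed mode; the
#'   scenario grid uses 10, 50, 100, 200, 300).
#' @param fixed_fi fire intensity (required in fixed mode; the scenario
#'   grid uses 0.1, 0.5, 1.0).
#' @param seed master RNG seed (all stochastic components derive named
#'   substreams from it, see [rng_streams()]).
#' @param spinup_years fire-free years before the configured fire mode
#'   starts.
#' @param snapshot_every spatial snapshot cadence, yr (0 disables).
#' @param target_fpr_mean calibration target for the mean annual ignition
#'   probability.
#' @param perturb_t,perturb_p,perturb_mortality sensitivity factors in
#'   {0.95, 1, 1.05}.
#' @param init_density_per_m2 initial stand density (larch-dominated) used
#'   to seed the spin-up.
#' @param fire list of fire-engine parameters, see [fire_params()].
#' @param forest list of demographic parameters, see [forest_params()].
#' @param fpr an [fpr_model()].
#' @return list of class `fl_config`.
#' @export
run_config <- function(fire_mode = c("climate_driven", "off", "fixed"),
                       fixed_fri = NULL, fixed_fi = NULL, seed = 1L,
                       spinup_years = 0L, snapshot_every = 100L,
                       target_fpr_mean = 0.03,
                       perturb_t = 1, perturb_p = 1, perturb_mortality = 1,
                       init_density_per_m2 = 0.05,
                       fire = fire_params(), forest = forest_params(),
                       fpr = fpr_model()) {
  fire_mode <- match.arg(fire_mode)
  if (fire_mode == "fixed") {
    if (is.null(fixed_fri) || is.null(fixed_fi))
      stop_fl("fixed fire mode requires fixed_fri and fixed_fi")
    stopifnot(fixed_fri >= 1, fixed_fi >= 0, fixed_fi <= 1)
  }
  ok <- c(0.95, 1, 1.05)
  for (f in c(perturb_t, perturb_p, perturb_mortality))
    if (!any(abs(f - ok) < 1e-9))
      stop_fl("perturbation factors must be one of 0.95, 1, 1.05")
  cfg <- list(fire_mode = fire_mode, fixed_fri = fixed_fri,
              fixed_fi = fixed_fi, seed = as.integer(seed),
              spinup_years = as.integer(spinup_years),
              snapshot_every = as.integer(snapshot_every),
              target_fpr_mean = target_fpr_mean,
              perturb_t = perturb_t, perturb_p = perturb_p,
              perturb_mortality = perturb_mortality,
              init_density_per_m2 = init_density_per_m2,
              fire = fire, forest = forest, fpr = fpr)
  class(cfg) <- "fl_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' Sections `forcing`, `landscape`, `species`, `fire`, and `run` mirror the
#' function arguments of the corresponding builders; missing entries fall
#' back to defaults. `forcing$climate_csv`, `landscape$dir`, and
#' `species$csv` name input files; `forcing$synthetic` /
#' `landscape$synthetic` request the built-in generators with the given
#' arguments.
#'
#' @param path YAML file path.
#' @return list with `config` (an `fl_config`), and any of `climate`,
#'   `landscape`, `traits` that the file specifies.
#' @export
read_run_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  out <- list()
  run <- y$run %||% list()
  fire_sec <- y$fire %||% list()
  fp <- do.call(fire_params, fire_sec[names(fire_sec) %in%
                                        names(formals(fire_params))])
  fo <- y$forest %||% list()
  fop <- do.call(forest_params, fo[names(fo) %in%
                                     names(formals(forest_params))])
  fprm <- if (!is.null(fire_sec$fpr_model))
    do.call(fpr_model, fire_sec$fpr_model) else fpr_model()
  args <- run[names(run) %in% names(formals(run_config))]
  args$fire <- fp; args$forest <- fop; args$fpr <- fprm
  for (nm in c("fixed_fri", "fixed_fi"))
    if (!is.null(fire_sec[[nm]]) && is.null(args[[nm]]))
      args[[nm]] <- fire_sec[[nm]]
  if (!is.null(fire_sec$mode) && is.null(args$fire_mode))
    args$fire_mode <- fire_sec$mode
  out$config <- do.call(run_config, args)
  frc <- y$forcing %||% list()
  if (!is.null(frc$climate_csv)) {
    out$climate <- read_climate_csv(frc$climate_csv)
  } else if (!is.null(frc$synthetic)) {
    out$climate <- do.call(generate_synthetic_climate, frc$synthetic)
  }
  lsc <- y$landscape %||% list()
  if (!is.null(lsc$dir)) {
    paths <- as.list(file.path(lsc$dir,
                               paste0(c("elevation", "slope", "twi",
                                        "water"), ".asc")))
    names(paths) <- c("elevation", "slope", "twi", "water")
    out$landscape <- read_landscape(paths)
  } else if (!is.null(lsc$synthetic)) {
    out$landscape <- do.call(generate_synthetic_landscape, lsc$synthetic)
  }
  spc <- y$species %||% list()
  out$traits <- if (!is.null(spc$csv)) read_species_csv(spc$csv)
  else species_defaults()
  out
}

# flatten a config for the run manifest
config_manifest <- function(cfg, extra = list()) {
  m <- unclass(cfg)
  m$fpr <- unclass(m$fpr)
  c(m, extra)
}
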