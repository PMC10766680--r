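#' Build a simulation from forcing, landscape, species, and configuration
#'
#' Precomputes the annual fire-weather table (calibrating FPR_ann to the
#' configured target mean over the supplied series when possible), seeds
#' the named RNG substreams from the master seed, and plants an initial
#' larch-dominated stand so that spin-up starts from a vegetated state.
#' Species whose active-layer requirement exceeds the initial thaw depth
#' are not planted; they can only invade later through establishment.
#'
#' @param landscape an `fl_landscape`.
#' @param climate an `fl_climate` (one row per month; the run length is the
#'   number of years in the series).
#' @param traits species trait table, default [species_defaults()].
#' @param config an [run_config()].
#' @return an environment of class `fl_simulation`.
#' @export
fl_simulation <- function(landscape, climate, traits = species_defaults(),
                          config = run_config()) {
  climate <- validate_climate(as.data.frame(climate))
  traits <- validate_species(traits)
  sim <- new.env(parent = emptyenv())
  sim$landscape <- landscape
  sim$traits <- traits
  sim$config <- config
  clim <- climate
  clim$t_mon <- clim$t_mon * config$perturb_t
  clim$p_mon <- clim$p_mon * config$perturb_p
  sim$climate <- clim
  sim$years <- sort(unique(clim$year))
  sim$gs_t <- growing_season_temp(clim)
  sim$ti <- thaw_index(clim)
  cal <- tryCatch(
    calibrate_fpr(clim, config$fpr, target_mean = config$target_fpr_mean),
    error = function(e) NULL)
  sim$calibration <- cal
  sim$fpr_tab <- if (!is.null(cal)) fpr_series(clim, config$fpr, cal) else {
    fs <- fpr_series(clim, config$fpr, fpr_calibration(scale = 1))
    fs$fpr_ann <- NA_real_
    fs
  }
  fparams <- config$fire
  fparams$mortality_factor <- fparams$mortality_factor *
    config$perturb_mortality
  sim$fire_params <- fparams
  sim$streams <- rng_streams(config$seed)
  sim$ground_seeds <- matrix(0, nrow = landscape$nf, ncol = nrow(traits))
  sim$next_id <- 1L
  sim$year_index <- 0L
  sim$annual <- vector("list", length(sim$years))
  sim$fires <- list()
  sim$snapshots <- list()
  sim$trees <- with_stream(sim$streams, "demography",
                           init_stand(landscape, traits,
                                      config$init_density_per_m2))
  if (nrow(sim$trees)) sim$next_id <- max(sim$trees$id) + 1L
  class(sim) <- "fl_simulation"
  sim
}

# initial stand: random positions on land, larch-dominated, heights spread
# over the size spectrum; species needing deeper thaw than the initial
# active layer are excluded
init_stand <- function(landscape, traits, density) {
  land_area <- sum(!landscape$water_fine) * landscape$fine_res^2
  n <- round(density * land_area)
  trees <- new_trees(0L)
  if (n <= 0) return(trees)
  al0 <- max(landscape$active_layer)
  admissible <- which(traits$min_active_layer_cm <= al0)
  if (!length(admissible)) return(trees)
  share <- ifelse(traits$deciduous[admissible], 1, 0.05)
  share[which.max(traits$seed_rain_per_m2_yr[admissible])] <- 4
  share <- share / sum(share)
  sp <- admissible[sample.int(length(admissible), n, replace = TRUE,
                              prob = share)]
  x <- runif(n) * landscape$width_m
  y <- runif(n) * landscape$height_m
  cell <- fine_index(landscape, x, y)
  keep <- !landscape$water_fine[cell]
  sp <- sp[keep]; x <- x[keep]; y <- y[keep]
  n <- length(sp)
  h <- runif(n, 30, 0.6 * traits$max_height_cm[sp])
  age <- pmax(1, round(h / traits$growth_rate_cm_yr[sp] * 2))
  df <- data.frame(id = seq_len(n), species = sp, x = x, y = y, height = h,
                   crown_base = 0.25 * h, age = age, alive = TRUE,
                   cone_seeds = 0, death_year = NA_integer_)
  class(df) <- c("fl_trees", "data.frame")
  df
}

#' @export
print.fl_simulation <- function(x, ...) {
  cat(sprintf("<fl_simulation> %d/%d years run, %d live trees, fire mode '%s'\n",
              x$year_index, length(x$years), sum(x$trees$alive),
              x$config$fire_mode))
  invisible(x)
}

#' Advance a simulation by one annual cycle
#'
#' Order of operations within a year: fire weather (FPR_ann) first; then
#' the fire step for the configured mode (climate-driven ignition,
#' placement, and impacts; or the scheduled whole-area scenario fire); then
#' demography (growth, seed production and dispersal, external seed rain,
#' establishment, natural mortality) so that post-fire establishment can
#' respond within the same year; then litter and active-layer updates; then
#' the annual record. Fire is suppressed during spin-up years.
#'
#' @param sim an `fl_simulation`.
#' @return the simulation, invisibly.
#' @export
run_annual_cycle <- function(sim) {
  i <- sim$year_index + 1L
  if (i > length(sim$years)) stop_fl("climate series exhausted")
  sim$year_index <- i
  year <- sim$years[i]
  cfg <- sim$config
  ls <- sim$landscape
  traits <- sim$traits
  fprow <- sim$fpr_tab[i, ]
  fpr <- fprow$fpr_ann
  in_spinup <- i <= cfg$spinup_years

  # --- fire step -----------------------------------------------------
  event <- NULL
  if (!in_spinup && cfg$fire_mode == "climate_driven" && !is.na(fpr) &&
      fpr > 0) {
    if (with_stream(sim$streams, "ignition", draw_ignition(fpr))) {
      geom <- with_stream(sim$streams, "placement",
                          place_fire(fpr, ls, sim$fire_params))
      event <- fire_event(year, fpr, geom, ls, sim$fire_params)
    }
  } else if (!in_spinup && cfg$fire_mode == "fixed") {
    elapsed <- i - cfg$spinup_years
    if (elapsed %% cfg$fixed_fri == 0L)
      event <- fire_event(year, ifelse(is.na(fpr), cfg$fixed_fi, fpr),
                          landscape = ls, params = sim$fire_params,
                          fixed_fi = cfg$fixed_fi)
  }
  fire_summary <- NULL
  if (!is.null(event) && event$burned_cells > 0L) {
    imp <- with_stream(sim$streams, "fire",
                       apply_fire(sim$trees, sim$ground_seeds, ls, event,
                                  traits, sim$fire_params))
    sim$trees <- imp$trees
    sim$ground_seeds <- imp$ground_seeds
    ls <- imp$landscape
    fire_summary <- imp$summary
    sim$fires[[length(sim$fires) + 1L]] <-
      c(list(year = year, center_x = event$center_x,
             center_y = event$center_y, diameter_m = event$diameter,
             fpr_ann = event$fpr_ann, burned_cells = event$burned_cells),
        fire_summary[c("cone_seeds_destroyed", "ground_seeds_destroyed",
                       "litter_removed_cm", "resprouted")],
        list(trees_killed = sum(fire_summary$trees_killed),
             seedlings_killed = sum(fire_summary$seedlings_killed)))
  }

  # --- demography ----------------------------------------------------
  with_stream(sim$streams, "demography", {
    trees <- sim$trees
    comp <- competition_index(trees, cfg$forest)
    trees <- annual_growth(trees, sim$gs_t[i], comp, traits, cfg$forest)
    pd <- produce_and_disperse(trees, sim$ground_seeds, ls, traits)
    trees <- pd$trees
    gs <- external_seed_rain(pd$ground_seeds, ls, traits)
    est <- establish(gs, ls, traits, sim$gs_t[i], sim$next_id, cfg$forest)
    sim$next_id <- est$next_id
    if (nrow(est$seedlings)) trees <- rbind(trees, est$seedlings)
    trees <- natural_mortality(trees, c(comp, numeric(nrow(trees) -
                                                        length(comp))),
                               year, traits, cfg$forest)
    sim$trees <- purge_dead(trees, year, cfg$forest)
    sim$ground_seeds <- est$ground_seeds
  })

  # --- litter and active layer --------------------------------------
  ls$litter <- with_stream(sim$streams, "disturbance",
                           update_litter(ls$litter, ls$water_fine,
                                         cfg$forest))
  ls$active_layer <- update_active_layer(ls$active_layer, sim$ti[i],
                                         ls$litter, ls$water_fine,
                                         cfg$forest)
  sim$landscape <- ls

  # --- annual record -------------------------------------------------
  met <- structure_metrics(sim$trees, traits)
  land <- !ls$water_fine
  rec <- c(list(year = year, fpr_ann = fpr,
                n_mild = fprow$n_mild, n_severe = fprow$n_severe,
                n_extreme = fprow$n_extreme,
                fire = !is.null(fire_summary),
                burned_cells = if (is.null(fire_summary)) 0L else
                  fire_summary$burned_cells),
           met[c("stem_count", "seedling_count", "mean_height_mature",
                 "evergreen_deciduous_ratio", "n_live")],
           list(mean_litter_cm = mean(ls$litter[land]),
                mean_active_layer_cm = mean(ls$active_layer[land])))
  stems_sp <- met$stems_per_species
  names(stems_sp) <- paste0("stems_", seq_along(stems_sp))
  sim$annual[[i]] <- c(rec, as.list(stems_sp))

  if (cfg$snapshot_every > 0L && i %% cfg$snapshot_every == 0L)
    sim$snapshots[[as.character(year)]] <- spatial_snapshot(sim, year)
  invisible(sim)
}

#' Run a simulation over its climate series
#'
#' @param sim an `fl_simulation`.
#' @param n_years number of years to advance (default: the remainder of the
#'   climate series).
#' @param progress print a progress line every 100 years.
#' @return the simulation, invisibly; retrieve outputs with
#'   [simulation_results()].
#' @export
fl_run <- function(sim, n_years = NULL, progress = FALSE) {
  n <- n_years %||% (length(sim$years) - sim$year_index)
  for (k in seq_len(n)) {
    run_annual_cycle(sim)
    if (progress && sim$year_index %% 100L == 0L)
      message(sprintf("year %d/%d, %d live trees", sim$year_index,
                      length(sim$years), sum(sim$trees$alive)))
  }
  invisible(sim)
}

#' Collect simulation outputs
#'
#' @param sim a run `fl_simulation`.
#' @return list with `annual` (one row per simulated year), `fires` (one
#'   row per fire event with impact tallies), and `snapshots` (per-coarse
#'   cell means of litter and active layer and per-species stem counts, at
#'   the snapshot cadence).
#' @export
simulation_results <- function(sim) {
  done <- seq_len(sim$year_index)
  annual <- do.call(rbind, lapply(sim$annual[done], function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  fires <- if (length(sim$fires))
    do.call(rbind, lapply(sim$fires, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
  else data.frame(year = integer(0), center_x = numeric(0),
                  center_y = numeric(0), diameter_m = numeric(0),
                  fpr_ann = numeric(0), burned_cells = integer(0),
                  cone_seeds_destroyed = numeric(0),
                  ground_seeds_destroyed = numeric(0),
                  litter_removed_cm = numeric(0), resprouted = integer(0),
                  trees_killed = integer(0), seedlings_killed = integer(0))
  list(annual = annual, fires = fires, snapshots = sim$snapshots)
}

# per-coarse-cell means and stem counts at a snapshot year
spatial_snapshot <- function(sim, year) {
  ls <- sim$landscape
  ncc <- ls$nxc * ls$nyc
  per <- ls$ratio^2
  litter <- rowsum(ls$litter, ls$f2c, reorder = TRUE)[, 1] / per
  active <- rowsum(ls$active_layer, ls$f2c, reorder = TRUE)[, 1] / per
  trees <- sim$trees
  live <- trees$alive & trees$height >= 130
  stems <- matrix(0L, nrow = ncc, ncol = nrow(sim$traits))
  if (any(live)) {
    cc <- ls$f2c[fine_index(ls, trees$x[live], trees$y[live])]
    for (s in unique(trees$species[live]))
      stems[, s] <- tabulate(cc[trees$species[live] == s], nbins = ncc)
  }
  list(year = year,
       litter = matrix(litter, ls$nyc, ls$nxc),
       active_layer = matrix(active, ls$nyc, ls$nxc),
       stems = stems)
}

#' Mean and spread of the fire return interval
#'
#' Intervals between consecutive fire years within a window; reports their
#' mean and population (divide-by-n) standard deviation.
#'
#' @param fire_years integer vector of fire years.
#' @param window optional `c(first, last)` year range.
#' @return list with `mean_fri`, `sd_fri`, `n_intervals`; `NA` values (with
#'   a warning) when fewer than two fires fall in the window.
#' @export
compute_fri_stats <- function(fire_years, window = NULL) {
  fy <- sort(unique(fire_years))
  if (!is.null(window)) fy <- fy[fy >= window[1] & fy <= window[2]]
  if (length(fy) < 2L) {
    warning("fewer than two fires in window; FRI undefined")
    return(list(mean_fri = NA_real_, sd_fri = NA_real_, n_intervals = 0L))
  }
  iv <- diff(fy)
  list(mean_fri = mean(iv),
       sd_fri = sqrt(mean((iv - mean(iv))^2)),
       n_intervals = length(iv))
}
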