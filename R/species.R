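#' Default species trait table
#'
#' Traits for the six boreal conifers of the eastern Siberian study system.
#' Establishment is gated by a species-specific minimum active layer depth
#' (Dahurian larch 20 cm; Scots pine 100 cm; Siberian spruce and Siberian
#' pine 200 cm), so the fire-deepened active layer controls which species
#' can recruit. Bark thickness is modeled as `bark_coef * height` (cm of
#' bark per cm of height) and insulates the stem against fire; only the
#' larches are deciduous and only they can resprout after fire top-kill.
#' Demographic rates (growth, seed output, dispersal, mortality, maximum
#' age/height) are stand-in values for a minimal demographic core, all
#' tunable through this table without code changes.
#'
#' @return data.frame, one row per species. Columns: `species`, `deciduous`,
#'   `min_active_layer_cm`, `bark_coef` (cm bark per cm height),
#'   `resprout_prob`, `growth_rate_cm_yr` (at climatic optimum, zero
#'   competition), `temp_optimum_c`, `temp_tolerance_c` (Gaussian
#'   suitability), `maturity_height_cm`, `max_height_cm`, `seeds_per_year`,
#'   `release_frac` (fraction of cone bank released annually),
#'   `dispersal_sd_m` (isotropic Gaussian kernel), `max_age_yr`,
#'   `background_mortality` (per yr), `seed_rain_per_m2_yr` (external seed
#'   influx from beyond the simulated area).
#' @export
species_defaults <- function() {
  df <- data.frame(
    species = c("Dahurian larch", "Cajander larch", "Siberian larch",
                "Siberian spruce", "Scots pine", "Siberian pine"),
    deciduous = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    min_active_layer_cm = c(20, 20, 20, 200, 100, 200),
    bark_coef = c(0.006, 0.0055, 0.005, 0.002, 0.004, 0.003),
    resprout_prob = c(0.25, 0.20, 0.15, 0, 0, 0),
    growth_rate_cm_yr = c(30, 26, 28, 20, 25, 18),
    temp_optimum_c = c(12, 11, 13, 13, 14, 12),
    temp_tolerance_c = c(6, 5, 5, 4, 4, 4),
    maturity_height_cm = c(200, 200, 200, 250, 250, 300),
    max_height_cm = c(1400, 1350, 1400, 1300, 1400, 1300),
    seeds_per_year = c(40, 30, 35, 30, 30, 25),
    release_frac = c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5),
    dispersal_sd_m = c(20, 20, 22, 15, 25, 18),
    max_age_yr = c(400, 400, 400, 350, 350, 450),
    background_mortality = c(0.015, 0.015, 0.015, 0.02, 0.018, 0.018),
    seed_rain_per_m2_yr = c(0.02, 0.002, 0.005, 0.004, 0.004, 0.003),
    stringsAsFactors = FALSE
  )
  class(df) <- c("fl_species", "data.frame")
  df
}

species_schema <- function() names(species_defaults())

validate_species <- function(traits) {
  need <- species_schema()
  if (!all(need %in% names(traits)))
    stop_fl("species table missing columns: %s",
            paste(setdiff(need, names(traits)), collapse = ", "))
  traits <- as.data.frame(traits)[need]
  if (any(traits$min_active_layer_cm <= 0))
    stop_fl("min_active_layer_cm must be > 0")
  if (any(traits$bark_coef < 0)) stop_fl("bark_coef must be >= 0")
  if (any(duplicated(traits$species))) stop_fl("duplicate species names")
  class(traits) <- c("fl_species", "data.frame")
  traits
}

#' Read or write a species trait table as CSV
#'
#' The CSV schema matches [species_defaults()]; a copy of the default table
#' ships in `inst/extdata/species_defaults.csv`.
#'
#' @param path CSV file path.
#' @return `read_species_csv`: a validated `fl_species` data.frame.
#' @export
read_species_csv <- function(path) {
  validate_species(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_species_csv
#' @param traits an `fl_species` data.frame.
#' @export
write_species_csv <- function(traits, path) {
  write.csv(validate_species(traits), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
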