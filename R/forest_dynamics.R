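#' Forest-dynamics parameters
#'
#' Tunable constants of the minimal demographic core. Litter and
#' active-layer constants are calibrated to the field-observed targets of
#' the study system: with disturbances off, litter regrows at exactly 0.5 cm
#' per year; with the shipped disturbance regime its long-run spatial mean
#' is about 13 cm; the Stefan-type active-layer equilibrium is about 60 cm
#' under cold-stage climate beneath 13 cm of litter and about 100 cm under
#' warm climate on bare ground.
#'
#' @param comp_radius_m neighborhood radius for competition, m.
#' @param comp_scale scale of the competition kernel.
#' @param m_comp maximum annual competition mortality increment.
#' @param age_exp exponent of the age mortality term `(age/max_age)^age_exp`.
#' @param germ_base per-seed germination probability on bare soil.
#' @param k_litter germination decay per cm of litter.
#' @param seed_decay annual ground-seed viability loss fraction.
#' @param seedling_height_cm initial height of a germinant, cm.
#' @param crown_frac equilibrium crown-base fraction of tree height.
#' @param crown_adjust annual relaxation of the crown base toward
#'   `crown_frac * height`.
#' @param snag_delay_yr years a dead tree is retained before removal.
#' @param litter_input_cm maximum annual litter accumulation, cm
#'   (needle-litter regeneration rate).
#' @param litter_cap_cm maximum litter height, cm.
#' @param litter_p_dist annual probability of a small-scale litter
#'   disturbance per fine cell (each removes a uniform random fraction).
#' @param stefan_coef active-layer coefficient, cm per sqrt(deg C day).
#' @param k_ins insulation decay of thaw depth per cm of litter.
#' @param al_tau_yr e-folding time of active-layer relaxation, yr.
#' @return list of parameters.
#' @export
forest_params <- function(comp_radius_m = 10, comp_scale = 0.012,
                          m_comp = 0.25, age_exp = 4,
                          germ_base = 0.03, k_litter = 0.2,
                          seed_decay = 0.5, seedling_height_cm = 1,
                          crown_frac = 0.35, crown_adjust = 0.2,
                          snag_delay_yr = 0,
                          litter_input_cm = 0.5, litter_cap_cm = 18,
                          litter_p_dist = 0.045,
                          stefan_coef = 2.24, k_ins = 0.013, al_tau_yr = 3) {
  as.list(environment())
}

#' Create an empty tree table
#'
#' Trees are rows of a data.frame: `id`, `species` (row index into the
#' trait table), continuous position `x`, `y` (m), `height` and
#' `crown_base` (cm, `0 <= crown_base < height`), `age` (yr), `alive`,
#' `cone_seeds` (seed bank held in cones), `death_year`.
#'
#' @param n number of empty rows.
#' @return a data.frame of class `fl_trees`.
#' @export
new_trees <- function(n = 0L) {
  df <- data.frame(id = integer(n), species = integer(n), x = numeric(n),
                   y = numeric(n), height = numeric(n),
                   crown_base = numeric(n), age = numeric(n),
                   alive = logical(n), cone_seeds = numeric(n),
                   death_year = rep(NA_integer_, n))
  class(df) <- c("fl_trees", "data.frame")
  df
}

#' Gaussian temperature suitability
#'
#' `exp(-((T - optimum)^2) / (2 tolerance^2))`: 1 at the species optimum,
#' falling off with distance in units of the tolerance.
#'
#' @param gs_t growing-season mean temperature, deg C (NA gives 0).
#' @param optimum,tolerance species trait values, deg C.
#' @return suitability in `[0, 1]`.
#' @export
temp_suitability <- function(gs_t, optimum, tolerance) {
  out <- exp(-((gs_t - optimum)^2) / (2 * tolerance^2))
  out[is.na(out)] <- 0
  out
}

#' Height-asymmetric competition index
#'
#' For each tree, the sum over taller-or-equal neighbors within
#' `comp_radius_m` of neighbor height (m) times a linear distance decay,
#' scaled by `comp_scale`. Zero for an isolated tree; adding a neighbor
#' never decreases the index.
#'
#' @param trees an `fl_trees` data.frame (dead trees, if present, are
#'   ignored).
#' @param params [forest_params()].
#' @return numeric vector, one index per row of `trees` (0 for dead rows).
#' @export
competition_index <- function(trees, params = forest_params()) {
  out <- numeric(nrow(trees))
  live <- which(trees$alive)
  if (length(live) > 1L) {
    out[live] <- competition_kernel_cpp(trees$x[live], trees$y[live],
                                        trees$height[live],
                                        params$comp_radius_m,
                                        params$comp_scale)
  }
  out
}

#' Annual height growth
#'
#' `dh = growth_rate * temp_suitability * 1 / (1 + competition)`, capped at
#' the species maximum height; the crown base relaxes toward a fixed
#' fraction of height (crowns lift as trees grow).
#'
#' @param trees an `fl_trees` data.frame.
#' @param gs_t growing-season mean temperature, deg C.
#' @param comp competition index per tree (see [competition_index()]).
#' @param traits species trait table.
#' @param params [forest_params()].
#' @return `trees` with updated `height`, `crown_base`, `age`.
#' @export
annual_growth <- function(trees, gs_t, comp, traits,
                          params = forest_params()) {
  live <- trees$alive
  sp <- trees$species[live]
  suit <- temp_suitability(gs_t, traits$temp_optimum_c[sp],
                           traits$temp_tolerance_c[sp])
  dh <- traits$growth_rate_cm_yr[sp] * suit / (1 + comp[live])
  h <- pmin(trees$height[live] + dh, traits$max_height_cm[sp])
  cb <- trees$crown_base[live]
  cb <- cb + params$crown_adjust * pmax(0, params$crown_frac * h - cb)
  trees$height[live] <- h
  trees$crown_base[live] <- pmin(cb, h - 1e-6)
  trees$age[live] <- trees$age[live] + 1
  trees
}

#' Seed production and isotropic dispersal
#'
#' Mature trees (height at or above the species maturity threshold) add
#' their annual seed output to the cone bank; a binomial share of the bank
#' is released and placed by an isotropic Gaussian kernel around the parent
#' (s.d. `dispersal_sd_m`). Seeds landing outside the area or on water are
#' discarded; the rest join the per-cell, per-species ground seed pool.
#'
#' @param trees an `fl_trees` data.frame.
#' @param ground_seeds numeric matrix, fine cells x species.
#' @param landscape an `fl_landscape`.
#' @param traits species trait table.
#' @return list with updated `trees` and `ground_seeds`.
#' @export
produce_and_disperse <- function(trees, ground_seeds, landscape, traits) {
  live <- which(trees$alive)
  if (!length(live)) return(list(trees = trees, ground_seeds = ground_seeds))
  sp <- trees$species[live]
  mature <- trees$height[live] >= traits$maturity_height_cm[sp]
  trees$cone_seeds[live[mature]] <- trees$cone_seeds[live[mature]] +
    traits$seeds_per_year[sp[mature]]
  idx <- live[mature]
  if (!length(idx)) return(list(trees = trees, ground_seeds = ground_seeds))
  cones <- trees$cone_seeds[idx]
  released <- rbinom(length(idx), round(cones),
                     traits$release_frac[trees$species[idx]])
  trees$cone_seeds[idx] <- cones - released
  tot <- sum(released)
  if (tot > 0) {
    src <- rep(seq_along(idx), released)
    sdm <- traits$dispersal_sd_m[trees$species[idx]][src]
    sx <- trees$x[idx][src] + rnorm(tot, 0, sdm)
    sy <- trees$y[idx][src] + rnorm(tot, 0, sdm)
    ssp <- trees$species[idx][src]
    keep <- sx >= 0 & sx < landscape$width_m & sy >= 0 &
      sy < landscape$height_m
    if (any(keep)) {
      cell <- fine_index(landscape, sx[keep], sy[keep])
      land <- !landscape$water_fine[cell]
      cell <- cell[land]; ssp <- ssp[keep][land]
      for (s in unique(ssp)) {
        tab <- tabulate(cell[ssp == s], nbins = landscape$nf)
        nz <- which(tab > 0L)
        ground_seeds[nz, s] <- ground_seeds[nz, s] + tab[nz]
      }
    }
  }
  list(trees = trees, ground_seeds = ground_seeds)
}

#' External seed rain
#'
#' Poisson seed influx from beyond the simulated area (`seed_rain_per_m2_yr`
#' per species), placed uniformly over land cells.
#'
#' @inheritParams produce_and_disperse
#' @return updated `ground_seeds`.
#' @export
external_seed_rain <- function(ground_seeds, landscape, traits) {
  land <- which(!landscape$water_fine)
  if (!length(land)) return(ground_seeds)
  area <- length(land) * landscape$fine_res^2
  for (s in seq_len(nrow(traits))) {
    n <- rpois(1, traits$seed_rain_per_m2_yr[s] * area)
    if (n > 0) {
      cells <- land[sample.int(length(land), n, replace = TRUE)]
      tab <- tabulate(cells, nbins = landscape$nf)
      nz <- which(tab > 0L)
      ground_seeds[nz, s] <- ground_seeds[nz, s] + tab[nz]
    }
  }
  ground_seeds
}

#' Seedling establishment
#'
#' Germination per seed is `germ_base * exp(-k_litter * litter) *
#' temp_suitability`, gated to zero where the active layer is shallower than
#' the species threshold. Germination draws are Poisson at the cell's
#' expected rate, capped by the pool; at most one germinant per fine cell,
#' species, and year survives to a seedling (self-thinning within a 0.04
#' m^2 cell). Germinated seeds are consumed; the remaining pool loses
#' viability at `seed_decay` per year.
#'
#' @inheritParams produce_and_disperse
#' @param gs_t growing-season mean temperature, deg C.
#' @param next_id first id to assign to new seedlings.
#' @param params [forest_params()].
#' @return list with `seedlings` (an `fl_trees` data.frame),
#'   `ground_seeds`, `next_id`.
#' @export
establish <- function(ground_seeds, landscape, traits, gs_t, next_id = 1L,
                      params = forest_params()) {
  ls <- landscape
  new_list <- vector("list", nrow(traits))
  for (s in seq_len(nrow(traits))) {
    idx <- which(ground_seeds[, s] > 0)
    if (!length(idx)) next
    ok <- ls$active_layer[idx] >= traits$min_active_layer_cm[s] &
      !ls$water_fine[idx]
    idx <- idx[ok]
    if (!length(idx)) next
    suit <- temp_suitability(gs_t, traits$temp_optimum_c[s],
                             traits$temp_tolerance_c[s])
    p <- params$germ_base * exp(-params$k_litter * ls$litter[idx]) * suit
    germ <- pmin(rpois(length(idx), ground_seeds[idx, s] * p),
                 ceiling(ground_seeds[idx, s]))
    hit <- which(germ > 0)
    if (length(hit)) {
      cells <- idx[hit]
      ground_seeds[cells, s] <- pmax(0, ground_seeds[cells, s] - germ[hit])
      ctr <- fine_center(ls, cells)
      n <- length(cells)
      jit <- ls$fine_res / 2
      new_list[[s]] <- data.frame(
        id = integer(n), species = s,
        x = ctr$x + runif(n, -jit, jit), y = ctr$y + runif(n, -jit, jit),
        height = params$seedling_height_cm,
        crown_base = 0, age = 0, alive = TRUE, cone_seeds = 0,
        death_year = NA_integer_)
    }
  }
  seedlings <- do.call(rbind, new_list[!vapply(new_list, is.null, TRUE)])
  if (is.null(seedlings)) seedlings <- new_trees(0L)
  if (nrow(seedlings)) {
    seedlings$id <- seq.int(next_id, length.out = nrow(seedlings))
    next_id <- next_id + nrow(seedlings)
  }
  class(seedlings) <- c("fl_trees", "data.frame")
  ground_seeds <- ground_seeds * (1 - params$seed_decay)
  ground_seeds[ground_seeds < 1e-3] <- 0
  list(seedlings = seedlings, ground_seeds = ground_seeds,
       next_id = next_id)
}

#' Annual death probability from background, age, and competition
#'
#' `p = background + (age / max_age)^age_exp + m_comp * comp / (1 + comp)`,
#' clamped to `[0, 1]`; certain death beyond the species maximum age.
#'
#' @param age,comp ages (yr) and competition indices.
#' @param species species row indices.
#' @param traits species trait table.
#' @param params [forest_params()].
#' @return death probabilities.
#' @export
mortality_prob <- function(age, comp, species, traits,
                           params = forest_params()) {
  p <- traits$background_mortality[species] +
    (age / traits$max_age_yr[species])^params$age_exp +
    params$m_comp * comp / (1 + comp)
  p[age > traits$max_age_yr[species]] <- 1
  clamp(p, 0, 1)
}

#' Natural (non-fire) mortality
#'
#' Draws deaths from [mortality_prob()]; dead trees are flagged (never
#' revived) and removed after the configured snag delay.
#'
#' @param trees an `fl_trees` data.frame.
#' @param comp competition index per tree.
#' @param year current simulation year (records `death_year`).
#' @inheritParams mortality_prob
#' @return updated `trees`.
#' @export
natural_mortality <- function(trees, comp, year, traits,
                              params = forest_params()) {
  live <- which(trees$alive)
  if (!length(live)) return(trees)
  p <- mortality_prob(trees$age[live], comp[live], trees$species[live],
                      traits, params)
  dead <- live[runif(length(live)) < p]
  trees$alive[dead] <- FALSE
  trees$death_year[dead] <- year
  trees
}

# drop dead rows past their snag retention window
purge_dead <- function(trees, year, params) {
  drop <- !trees$alive & (year - trees$death_year) >= params$snag_delay_yr
  if (any(drop)) trees <- trees[!drop, , drop = FALSE]
  trees
}

#' Annual litter-layer update
#'
#' Litter accumulates at up to `litter_input_cm` per year (0.5 cm, the
#' needle-litter regeneration rate) toward `litter_cap_cm`. With
#' disturbances on, each land cell is independently hit with probability
#' `litter_p_dist` per year and loses a uniform random fraction of its
#' litter; the shipped parameters give a long-run spatial mean of about 13
#' cm. Water cells stay at zero.
#'
#' @param litter numeric vector of fine-cell litter heights, cm.
#' @param water_fine logical vector flagging water cells.
#' @param params [forest_params()].
#' @param disturb logical; with `FALSE`, regrowth is exactly deterministic.
#' @param input_factor optional scalar or per-cell factor on the litter
#'   input (deciduous foliage availability; default 1 = closed larch
#'   canopy).
#' @return updated litter vector.
#' @export
update_litter <- function(litter, water_fine, params = forest_params(),
                          disturb = TRUE, input_factor = 1) {
  l <- pmin(litter + params$litter_input_cm * input_factor,
            params$litter_cap_cm)
  if (disturb && params$litter_p_dist > 0) {
    hit <- which(runif(length(l)) < params$litter_p_dist & !water_fine)
    if (length(hit)) l[hit] <- l[hit] * (1 - runif(length(hit)))
  }
  l[water_fine] <- 0
  pmax(l, 0)
}

#' Annual active-layer update
#'
#' The equilibrium thaw depth follows a Stefan-type square-root law in the
#' annual thaw index, damped exponentially by litter insulation:
#' `eq = stefan_coef * sqrt(thaw_index) * exp(-k_ins * litter)`. The actual
#' depth relaxes toward the equilibrium with e-folding time `al_tau_yr`
#' (multi-year thermal memory); removing litter strictly deepens the
#' equilibrium.
#'
#' @param active_layer numeric vector of fine-cell depths, cm.
#' @param ti annual thaw index, deg C days (see [thaw_index()]).
#' @param litter fine-cell litter heights, cm.
#' @param water_fine logical vector flagging water cells.
#' @param params [forest_params()].
#' @return updated active-layer vector.
#' @export
update_active_layer <- function(active_layer, ti, litter, water_fine,
                                params = forest_params()) {
  eq <- params$stefan_coef * sqrt(max(ti, 0)) * exp(-params$k_ins * litter)
  al <- active_layer + (eq - active_layer) * (1 - exp(-1 / params$al_tau_yr))
  al[water_fine] <- 0
  al
}
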