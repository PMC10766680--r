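#' Bark thickness from tree height
#'
#' Insulating bark thickness is height-dependent: `bark_coef * height` (cm
#' of bark per cm of height), so taller trees of thick-barked species are
#' better protected against stem heating.
#'
#' @param height tree heights, cm.
#' @param species species row indices.
#' @param traits species trait table.
#' @return bark thickness, cm.
#' @export
bark_thickness <- function(height, species, traits) {
  traits$bark_coef[species] * height
}

# fire intensity experienced by each tree: mean intensity over the fine
# cells its stem footprint touches (point stem in one cell below 2 m
# height; taller stems use a height-proportional disk radius and average
# the cells under its bounding corners)
tree_fire_intensity <- function(trees, event, landscape) {
  n <- nrow(trees)
  if (!n) return(numeric(0))
  fi <- fi_at_cells(event, fine_index(landscape, trees$x, trees$y),
                    landscape$nf)
  tall <- which(trees$height >= 200)
  if (length(tall)) {
    r <- trees$height[tall] * 5e-5          # stem radius in m (~1% DBH rule)
    acc <- numeric(length(tall))
    for (sx in c(-1, 1)) for (sy in c(-1, 1)) {
      cx <- clamp(trees$x[tall] + sx * r, 0, landscape$width_m - 1e-9)
      cy <- clamp(trees$y[tall] + sy * r, 0, landscape$height_m - 1e-9)
      acc <- acc + fi_at_cells(event, fine_index(landscape, cx, cy),
                               landscape$nf)
    }
    fi[tall] <- acc / 4
  }
  fi
}

#' Fire-induced tree mortality and resprouting
#'
#' Death combines two independent hazards: stem heating, attenuated by bark
#' insulation (`p_stem = fi * exp(-k_bark * bark)`), and crown damage from
#' scorch, where the scorched fraction of the live crown (crown base to tip,
#' against [flame_height()]) enters as `p_canopy = fraction^gamma_canopy`.
#' `p_kill = 1 - (1 - p_stem)(1 - p_canopy)`, times the sensitivity
#' multiplier. At intensity 1 the flame height exceeds every attainable
#' tree height, the crown is fully scorched, and death is certain
#' (stand-replacing fire). Top-killed larches resprout with their species
#' probability, restarting at a fraction of their pre-fire height.
#'
#' @param trees an `fl_trees` data.frame.
#' @param fi fire intensity experienced by each tree (`[0, 1]`).
#' @param traits species trait table.
#' @param params [fire_params()].
#' @param year simulation year (records `death_year`).
#' @return list with updated `trees` and logical vectors `killed` (died,
#'   incl. top-kills that resprouted) and `resprouted`.
#' @export
tree_fire_mortality <- function(trees, fi, traits, params = fire_params(),
                                year = NA_integer_) {
  live <- which(trees$alive & fi > 0)
  n0 <- length(live)
  if (!n0)
    return(list(trees = trees, killed = logical(nrow(trees)),
                resprouted = logical(nrow(trees))))
  sp <- trees$species[live]
  p_kill <- fire_kill_prob(fi[live], trees$height[live],
                           trees$crown_base[live], sp, traits, params)
  top_killed <- runif(n0) < p_kill
  resp <- top_killed & (runif(n0) < traits$resprout_prob[sp])
  died <- live[top_killed & !resp]
  trees$alive[died] <- FALSE
  trees$death_year[died] <- year
  rs <- live[resp]
  if (length(rs)) {
    h <- pmax(trees$height[rs] * params$resprout_height_frac, 1)
    trees$height[rs] <- h
    trees$crown_base[rs] <- pmin(trees$crown_base[rs], h / 2)
    trees$cone_seeds[rs] <- 0
  }
  killed <- resprouted <- logical(nrow(trees))
  killed[live[top_killed]] <- TRUE
  resprouted[rs] <- TRUE
  list(trees = trees, killed = killed, resprouted = resprouted)
}

#' @rdname tree_fire_mortality
#' @param height,crown_base tree dimensions, cm.
#' @param species species row indices.
#' @return for `fire_kill_prob`, the kill probability per tree.
#' @export
fire_kill_prob <- function(fi, height, crown_base, species, traits,
                           params = fire_params()) {
  bark <- bark_thickness(height, species, traits)
  p_stem <- fi * exp(-params$k_bark * bark)
  hs <- flame_height(fi, params)                     # m
  crown_len <- pmax(height - crown_base, 1e-9) / 100 # m
  scorched <- clamp(hs - crown_base / 100, 0, crown_len)
  p_canopy <- (scorched / crown_len)^params$gamma_canopy
  clamp((1 - (1 - p_stem) * (1 - p_canopy)) * params$mortality_factor, 0, 1)
}

#' Fire impacts on seed pools
#'
#' Ground seeds are removed entirely wherever fire intensity is above zero;
#' seeds held in cones are destroyed independently, each with probability
#' equal to the tree's local fire intensity.
#'
#' @param ground_seeds numeric matrix, fine cells x species.
#' @param cells fine-cell indices with intensity above zero.
#' @param trees an `fl_trees` data.frame.
#' @param fi_tree fire intensity experienced by each tree.
#' @return list with `ground_seeds`, `trees`, `ground_destroyed`,
#'   `cone_destroyed`.
#' @export
burn_seed_pools <- function(ground_seeds, cells, trees, fi_tree) {
  ground_destroyed <- sum(ground_seeds[cells, , drop = FALSE])
  ground_seeds[cells, ] <- 0
  cone_destroyed <- 0
  idx <- which(trees$alive & fi_tree > 0 & trees$cone_seeds > 0)
  if (length(idx)) {
    lost <- rbinom(length(idx), round(trees$cone_seeds[idx]), fi_tree[idx])
    trees$cone_seeds[idx] <- pmax(0, trees$cone_seeds[idx] - lost)
    cone_destroyed <- sum(lost)
  }
  list(ground_seeds = ground_seeds, trees = trees,
       ground_destroyed = ground_destroyed,
       cone_destroyed = cone_destroyed)
}

#' Fire impact on the litter layer
#'
#' Partial to complete removal: `height * max(0, 1 - fi / fi_full)`, with
#' complete removal at or above `fi_full`.
#'
#' @param litter fine-cell litter heights, cm.
#' @param cells fine-cell indices with intensity above zero.
#' @param fi their intensities.
#' @param params [fire_params()].
#' @return updated litter vector.
#' @export
burn_litter <- function(litter, cells, fi, params = fire_params()) {
  litter[cells] <- litter[cells] * pmax(0, 1 - fi / params$fi_full)
  litter
}

#' Apply a fire event to the full simulation state
#'
#' Orchestrates tree mortality, seed-pool destruction, and litter removal
#' over the event footprint, each entity affected exactly once, and tallies
#' a fire impact summary consistent with the entity-level changes.
#'
#' @param trees an `fl_trees` data.frame.
#' @param ground_seeds numeric matrix, fine cells x species.
#' @param landscape an `fl_landscape` (its `litter` and `last_fire` are
#'   updated).
#' @param event an [fire_event()].
#' @param traits species trait table.
#' @param params [fire_params()].
#' @return list with updated `trees`, `ground_seeds`, `landscape`, and
#'   `summary`: `year`, per-species `trees_killed` (>= 130 cm) and
#'   `seedlings_killed` (< 130 cm), `resprouted`, `cone_seeds_destroyed`,
#'   `ground_seeds_destroyed`, `litter_removed_cm` (mean over burned
#'   cells), `burned_cells`.
#' @export
apply_fire <- function(trees, ground_seeds, landscape, event, traits,
                       params = fire_params()) {
  n_sp <- nrow(traits)
  fi_tree <- tree_fire_intensity(trees, event, landscape)
  pre_height <- trees$height
  mort <- tree_fire_mortality(trees, fi_tree, traits, params,
                              year = event$year)
  seeds <- burn_seed_pools(ground_seeds, event$cells, mort$trees, fi_tree)
  litter_before <- if (length(event$cells))
    mean(landscape$litter[event$cells]) else 0
  landscape$litter <- burn_litter(landscape$litter, event$cells, event$fi,
                                  params)
  litter_after <- if (length(event$cells))
    mean(landscape$litter[event$cells]) else 0
  landscape$last_fire[event$cells] <- event$year
  killed_mature <- mort$killed & !mort$resprouted & pre_height >= 130
  killed_seedl <- mort$killed & !mort$resprouted & pre_height < 130
  summary <- list(
    year = event$year,
    trees_killed = tabulate(trees$species[killed_mature], nbins = n_sp),
    seedlings_killed = tabulate(trees$species[killed_seedl], nbins = n_sp),
    resprouted = sum(mort$resprouted),
    cone_seeds_destroyed = seeds$cone_destroyed,
    ground_seeds_destroyed = seeds$ground_destroyed,
    litter_removed_cm = litter_before - litter_after,
    burned_cells = event$burned_cells
  )
  list(trees = seeds$trees, ground_seeds = seeds$ground_seeds,
       landscape = landscape, summary = summary)
}
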