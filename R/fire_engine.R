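#' Fire-engine parameters
#'
#' @param twi_wet_frac position of the wetness cutoff within the landscape
#'   TWI range: cells with TWI at or above `twi_min + twi_wet_frac *
#'   (twi_max - twi_min)` are too wet to burn (intensity 0).
#' @param h_max_m flame height at intensity 1, m. Must exceed the tallest
#'   attainable tree so that a stand-replacing fire scorches every crown
#'   completely.
#' @param flame_exp flame-height exponent `h = h_max * FI^flame_exp`.
#'   The default (1.7) is calibrated jointly with `k_bark` and
#'   `gamma_canopy` so that the three canonical fire regimes emerge: a
#'   low-intensity (0.1) surface fire leaves the mature stem count
#'   visibly unchanged, a medium (0.5) fire is survivable for tall
#'   larches, and intensity 1.0 is stand-replacing. A sublinear
#'   plume-scaling exponent (e.g. 0.4) can be configured instead; only
#'   monotonicity matters downstream.
#' @param diameter_exp exponent of the fire-diameter law `diameter = width *
#'   FPR_ann^diameter_exp` (1 = linear).
#' @param k_bark stem-damage attenuation per cm of bark.
#' @param gamma_canopy exponent on the crown scorch fraction.
#' @param fi_full intensity at which the litter layer is removed completely.
#' @param resprout_height_frac height fraction retained by a resprouting
#'   top-killed tree.
#' @param mortality_factor multiplier on fire kill probability (used by the
#'   +/-5 percent sensitivity runs).
#' @return list of fire parameters.
#' @export
fire_params <- function(twi_wet_frac = 0.8, h_max_m = 15, flame_exp = 1.7,
                        diameter_exp = 1, k_bark = 1.5, gamma_canopy = 4,
                        fi_full = 0.8, resprout_height_frac = 0.1,
                        mortality_factor = 1) {
  list(twi_wet_frac = twi_wet_frac, h_max_m = h_max_m,
       flame_exp = flame_exp, diameter_exp = diameter_exp, k_bark = k_bark,
       gamma_canopy = gamma_canopy, fi_full = fi_full,
       resprout_height_frac = resprout_height_frac,
       mortality_factor = mortality_factor)
}

#' Draw an annual ignition
#'
#' One fire at most can occur per simulated year: a uniform draw below the
#' annual fire probability rating ignites it.
#'
#' @param fpr_ann annual ignition probability in `[0, 1]`.
#' @return logical, `TRUE` with probability `fpr_ann`.
#' @export
draw_ignition <- function(fpr_ann) {
  stopifnot(fpr_ann >= 0, fpr_ann <= 1)
  runif(1) < fpr_ann
}

#' Place a fire on the landscape
#'
#' The center is uniform over the simulation rectangle; the affected
#' diameter scales with FPR_ann relative to the area width (linear by
#' default, so FPR_ann = 1 spans the whole area). The disk is clipped at the
#' area boundary.
#'
#' @param fpr_ann annual ignition probability (ignition already drawn).
#' @param landscape an `fl_landscape`.
#' @param params [fire_params()].
#' @return list with `center_x`, `center_y`, `diameter` (m).
#' @export
place_fire <- function(fpr_ann, landscape, params = fire_params()) {
  list(center_x = runif(1) * landscape$width_m,
       center_y = runif(1) * landscape$height_m,
       diameter = landscape$width_m * fpr_ann^params$diameter_exp)
}

#' Per-cell fire intensity mediated by the topographic wetness index
#'
#' `FI = fpr_ann * max(0, 1 - (twi - twi_min) / (twi_wet - twi_min))`:
#' intensity equals the annual rating on the driest cells and falls linearly
#' to zero at the wetness cutoff `twi_wet`; wetter cells do not burn at all.
#'
#' @param fpr_ann annual ignition probability.
#' @param twi cell TWI values (vectorized).
#' @param twi_min landscape minimum TWI over land.
#' @param twi_wet wetness cutoff (must exceed `twi_min`).
#' @return fire intensity in `[0, 1]`.
#' @export
cell_intensity <- function(fpr_ann, twi, twi_min, twi_wet) {
  stopifnot(twi_wet > twi_min)
  fpr_ann * clamp(1 - (twi - twi_min) / (twi_wet - twi_min), 0, 1)
}

#' Flame (scorch) height from fire intensity
#'
#' Plume-type power scaling `h = h_max * FI^flame_exp`, zero at zero
#' intensity; monotone increasing and concave for `flame_exp < 1`.
#'
#' @param fi fire intensity in `[0, 1]`.
#' @param params [fire_params()].
#' @return scorch height, m.
#' @export
flame_height <- function(fi, params = fire_params()) {
  stopifnot(all(fi >= 0), all(fi <= 1))
  params$h_max_m * fi^params$flame_exp
}

#' Build a fire event's intensity field
#'
#' For a climate-driven fire, every non-water fine cell within the placed
#' disk receives [cell_intensity()] inherited from its containing coarse
#' cell; cells at or above the wetness cutoff burn at intensity zero and are
#' excluded from the burned-cell count. For a fixed-scenario fire
#' (`fixed_fi` given) the whole land area burns at exactly `fixed_fi`,
#' without TWI mediation, so scenario intensities are as labeled.
#'
#' @param year simulation year of the event.
#' @param fpr_ann annual rating at the event.
#' @param geometry list with `center_x`, `center_y`, `diameter` from
#'   [place_fire()]; ignored in fixed mode.
#' @param landscape an `fl_landscape`.
#' @param params [fire_params()].
#' @param fixed_fi if non-`NULL`, a whole-area fire at this intensity.
#' @return an object of class `fl_fire_event`: `year`, `center_x`,
#'   `center_y`, `diameter`, `fpr_ann`, `cells` (fine-cell indices with FI >
#'   0), `fi` (their intensities), `burned_cells`.
#' @export
fire_event <- function(year, fpr_ann, geometry = NULL, landscape,
                       params = fire_params(), fixed_fi = NULL) {
  ls <- landscape
  if (!is.null(fixed_fi)) {
    stopifnot(fixed_fi >= 0, fixed_fi <= 1)
    cells <- which(!ls$water_fine)
    fi <- rep(fixed_fi, length(cells))
    keep <- fi > 0
    ev <- list(year = year, center_x = ls$width_m / 2,
               center_y = ls$height_m / 2, diameter = ls$width_m,
               fpr_ann = fpr_ann, cells = cells[keep], fi = fi[keep],
               burned_cells = sum(keep))
    class(ev) <- "fl_fire_event"
    return(ev)
  }
  r <- geometry$diameter / 2
  res <- ls$fine_res
  # bounding box of the disk in fine-cell indices
  ix0 <- max(1L, floor((geometry$center_x - r) / res) + 1L)
  ix1 <- min(ls$nxf, floor((geometry$center_x + r) / res) + 1L)
  iy0 <- max(1L, floor((geometry$center_y - r) / res) + 1L)
  iy1 <- min(ls$nyf, floor((geometry$center_y + r) / res) + 1L)
  if (ix1 < ix0 || iy1 < iy0 || r <= 0) {
    ev <- list(year = year, center_x = geometry$center_x,
               center_y = geometry$center_y, diameter = geometry$diameter,
               fpr_ann = fpr_ann, cells = integer(0), fi = numeric(0),
               burned_cells = 0L)
    class(ev) <- "fl_fire_event"
    return(ev)
  }
  ix <- ix0:ix1; iy <- iy0:iy1
  cx <- (ix - 0.5) * res; cy <- (iy - 0.5) * res
  inside <- outer(cy - geometry$center_y, cx - geometry$center_x,
                  function(dy, dx) dx * dx + dy * dy) <= r * r
  # linear fine indices of the bounding box block (column-major, x in cols)
  idx <- as.vector(outer(iy, (ix - 1L) * ls$nyf, `+`))[as.vector(inside)]
  idx <- idx[!ls$water_fine[idx]]
  twi_wet <- ls$twi_min + params$twi_wet_frac * (ls$twi_max - ls$twi_min)
  fi <- cell_intensity(fpr_ann, as.vector(ls$twi)[ls$f2c[idx]],
                       ls$twi_min, twi_wet)
  keep <- fi > 0
  ev <- list(year = year, center_x = geometry$center_x,
             center_y = geometry$center_y, diameter = geometry$diameter,
             fpr_ann = fpr_ann, cells = idx[keep], fi = fi[keep],
             burned_cells = sum(keep))
  class(ev) <- "fl_fire_event"
  ev
}

#' @export
print.fl_fire_event <- function(x, ...) {
  cat(sprintf("<fl_fire_event> year %s: center (%.0f, %.0f) m, diameter %.1f m, %d burned cells\n",
              format(x$year), x$center_x, x$center_y, x$diameter,
              x$burned_cells))
  invisible(x)
}

# fire intensity at queried fine cells (0 outside the event footprint)
fi_at_cells <- function(event, idx, nf) {
  if (length(event$cells) > nf / 4L) {
    full <- numeric(nf)
    full[event$cells] <- event$fi
    full[idx]
  } else {
    m <- match(idx, event$cells)
    out <- event$fi[m]
    out[is.na(m)] <- 0
    out
  }
}
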