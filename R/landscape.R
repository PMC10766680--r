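#' Read or write a single-layer ESRI ASCII grid
#'
#' Minimal reader/writer for the plain-text ESRI ASCII raster format
#' (`ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value` header followed
#' by rows from north to south). Internally grids are matrices with row 1 at
#' the southern edge, `[row = y index, col = x index]`.
#'
#' @param path file path.
#' @return `read_esri_ascii`: a matrix with attributes `xllcorner`,
#'   `yllcorner`, `cellsize`, `nodata`; NODATA cells are `NA`.
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path, n = 6L)
  kv <- strsplit(trimws(lines), "\\s+")
  keys <- tolower(vapply(kv, `[`, character(1), 1L))
  vals <- as.numeric(vapply(kv, `[`, character(1), 2L))
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% keys))
    stop_fl("%s: malformed ESRI ASCII header", path)
  nc <- as.integer(vals[["ncols"]]); nr <- as.integer(vals[["nrows"]])
  dat <- scan(path, skip = 6L, quiet = TRUE)
  if (length(dat) != nc * nr)
    stop_fl("%s: expected %d values, found %d", path, nc * nr, length(dat))
  m <- matrix(dat, nrow = nr, ncol = nc, byrow = TRUE)
  m <- m[nr:1, , drop = FALSE]          # file is north-to-south; flip to south-up
  m[m == vals[["nodata_value"]]] <- NA_real_
  structure(m, xllcorner = vals[["xllcorner"]], yllcorner = vals[["yllcorner"]],
            cellsize = vals[["cellsize"]], nodata = vals[["nodata_value"]])
}

#' @rdname read_esri_ascii
#' @param m matrix (row 1 = southern edge).
#' @param xllcorner,yllcorner lower-left corner coordinates, m.
#' @param cellsize cell edge length, m.
#' @param nodata NODATA sentinel written for `NA` cells.
#' @export
write_esri_ascii <- function(m, path, xllcorner = 0, yllcorner = 0,
                             cellsize = 90, nodata = -9999) {
  hdr <- c(sprintf("ncols %d", ncol(m)), sprintf("nrows %d", nrow(m)),
           sprintf("xllcorner %.6g", xllcorner),
           sprintf("yllcorner %.6g", yllcorner),
           sprintf("cellsize %.6g", cellsize),
           sprintf("NODATA_value %.6g", nodata))
  mm <- m[nrow(m):1, , drop = FALSE]
  mm[is.na(mm)] <- nodata
  body <- apply(mm, 1L, function(r) paste(format(r, trim = TRUE), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Construct a simulation landscape
#'
#' A landscape couples a coarse raster stack (elevation m a.s.l., slope
#' degrees, topographic wetness index, water mask) at `coarse_res` (default
#' 90 m) with a fine sub-grid (default 0.2 m) carrying per-cell state:
#' litter height (cm), active layer depth (cm), and the year of last fire.
#' The fine grid tiles the coarse grid exactly. Water cells carry no litter
#' and can never hold trees or seeds.
#'
#' @param elevation,slope,twi numeric matrices (row 1 = southern edge).
#' @param water logical matrix, `TRUE` for water cells.
#' @param coarse_res,fine_res cell sizes in m; `coarse_res` must be an exact
#'   multiple of `fine_res`.
#' @param litter_init initial litter height on land, cm (field-observed
#'   organic-layer equilibrium of about 13 cm).
#' @param active_init initial active layer depth, cm.
#' @return an object of class `fl_landscape`.
#' @export
new_landscape <- function(elevation, slope, twi, water,
                          coarse_res = 90, fine_res = 0.2,
                          litter_init = 13, active_init = 60) {
  dm <- dim(elevation)
  for (nm in c("slope", "twi", "water")) {
    if (!identical(dim(get(nm)), dm))
      stop_fl("landscape layer '%s' shape mismatch", nm)
  }
  ratio <- coarse_res / fine_res
  if (abs(ratio - round(ratio)) > 1e-9)
    stop_fl("coarse_res must be an exact multiple of fine_res")
  ratio <- as.integer(round(ratio))
  water <- water & !is.na(water)
  if (any(is.na(elevation) & !water) || any(is.na(twi) & !water) ||
      any(is.na(slope) & !water))
    stop_fl("NODATA in non-water landscape cells")
  nyc <- dm[1]; nxc <- dm[2]
  nyf <- nyc * ratio; nxf <- nxc * ratio
  # fine -> coarse linear index (column-major, columns along x)
  f2c <- as.vector(outer(ceiling(seq_len(nyf) / ratio),
                         (ceiling(seq_len(nxf) / ratio) - 1L) * nyc, `+`))
  water_fine <- as.vector(water)[f2c]
  nf <- nxf * nyf
  ls <- list(
    elevation = elevation, slope = slope, twi = twi, water = water,
    coarse_res = coarse_res, fine_res = fine_res, ratio = ratio,
    nxc = nxc, nyc = nyc, nxf = nxf, nyf = nyf, nf = nf,
    width_m = nxc * coarse_res, height_m = nyc * coarse_res,
    f2c = f2c, water_fine = water_fine,
    litter = ifelse(water_fine, 0, litter_init),
    active_layer = ifelse(water_fine, 0, active_init),
    last_fire = rep(NA_integer_, nf)
  )
  land <- !water & !is.na(twi)
  ls$twi_min <- if (any(land)) min(twi[land]) else NA_real_
  ls$twi_max <- if (any(land)) max(twi[land]) else NA_real_
  class(ls) <- "fl_landscape"
  ls
}

#' @export
print.fl_landscape <- function(x, ...) {
  cat(sprintf("<fl_landscape> %g x %g m (%d x %d coarse cells at %g m, %d fine cells at %g m)\n",
              x$width_m, x$height_m, x$nxc, x$nyc, x$coarse_res, x$nf,
              x$fine_res))
  cat(sprintf("  water fraction %.2f; TWI range [%.2f, %.2f]\n",
              mean(x$water), x$twi_min, x$twi_max))
  invisible(x)
}

# fine-cell linear index of continuous coordinates (half-open cells
# [i*res, (i+1)*res), origin at the south-west corner)
fine_index <- function(ls, x, y) {
  ix <- pmin(pmax(floor(x / ls$fine_res), 0L), ls$nxf - 1L) + 1L
  iy <- pmin(pmax(floor(y / ls$fine_res), 0L), ls$nyf - 1L) + 1L
  (ix - 1L) * ls$nyf + iy
}

# centers of fine cells for a vector of linear indices
fine_center <- function(ls, idx) {
  iy <- ((idx - 1L) %% ls$nyf) + 1L
  ix <- ((idx - 1L) %/% ls$nyf) + 1L
  list(x = (ix - 0.5) * ls$fine_res, y = (iy - 0.5) * ls$fine_res)
}

#' Read a landscape from ESRI ASCII grid files
#'
#' @param paths named list or character vector with entries `elevation`,
#'   `slope`, `twi`, `water` (water: 1 = water, 0 = land).
#' @param ... passed to [new_landscape()].
#' @return an `fl_landscape`.
#' @export
read_landscape <- function(paths, ...) {
  need <- c("elevation", "slope", "twi", "water")
  if (!all(need %in% names(paths)))
    stop_fl("paths must name %s", paste(need, collapse = ", "))
  layers <- lapply(paths[need], read_esri_ascii)
  ref <- layers[[1]]
  for (nm in need[-1]) {
    l <- layers[[nm]]
    if (!identical(dim(l), dim(ref)))
      stop_fl("raster '%s': shape mismatch", nm)
    if (abs(attr(l, "cellsize") - attr(ref, "cellsize")) > 1e-9 ||
        abs(attr(l, "xllcorner") - attr(ref, "xllcorner")) > 1e-6 ||
        abs(attr(l, "yllcorner") - attr(ref, "yllcorner")) > 1e-6)
      stop_fl("raster '%s': resolution/origin mismatch", nm)
  }
  water <- !is.na(layers$water) & layers$water > 0
  new_landscape(layers$elevation, layers$slope, layers$twi, water,
                coarse_res = attr(ref, "cellsize"), ...)
}

#' @rdname read_landscape
#' @param ls an `fl_landscape`.
#' @param dir output directory (created if missing).
#' @export
write_landscape <- function(ls, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wm <- ls$water * 1
  layers <- list(elevation = ls$elevation, slope = ls$slope, twi = ls$twi,
                 water = wm)
  for (nm in names(layers)) {
    write_esri_ascii(layers[[nm]], file.path(dir, paste0(nm, ".asc")),
                     cellsize = ls$coarse_res)
  }
  invisible(dir)
}

#' Generate a synthetic landscape from a fractal elevation model
#'
#' Synthesizes a digital elevation model by spectral (Fourier) filtering of
#' white noise with a power-law spectrum, derives slope from central
#' differences and a topographic wetness index `ln(contributing area /
#' tan(slope))` from single-flow-direction (steepest-descent) accumulation,
#' and flags the lowest-lying fraction of cells as water. The TWI field is
#' rescaled linearly onto `twi_range` (default matches the study region's
#' observed range, 7.1 to 15.5).
#'
#' @param n_coarse coarse cells per side (>= 2).
#' @param coarse_res coarse cell size, m.
#' @param relief_amplitude_m half-range of the synthetic relief, m.
#' @param roughness spectral decay exponent (larger = smoother terrain).
#' @param water_fraction fraction of cells flagged as water (lowest-lying).
#' @param twi_range target `c(min, max)` of TWI on land, or `NULL` to keep
#'   the raw values.
#' @param base_elevation_m elevation added to the relief, m a.s.l.
#' @param seed optional integer seed; same seed gives identical rasters.
#' @inheritParams new_landscape
#' @return an `fl_landscape`.
#' @export
generate_synthetic_landscape <- function(n_coarse, coarse_res = 90,
                                         fine_res = 0.2,
                                         relief_amplitude_m = 8,
                                         roughness = 1.8,
                                         water_fraction = 0.05,
                                         twi_range = c(7.1, 15.5),
                                         base_elevation_m = 106,
                                         litter_init = 13, active_init = 60,
                                         seed = NULL) {
  stopifnot(n_coarse >= 2)
  if (!is.null(seed)) set.seed(seed)
  n <- n_coarse
  if (relief_amplitude_m > 0) {
    kx <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))[1:n] / n
    k <- sqrt(outer(kx^2, kx^2, `+`))
    k[1, 1] <- Inf                       # kill the DC component
    amp <- k^(-roughness)
    phase <- matrix(runif(n * n, 0, 2 * pi), n, n)
    spec <- amp * exp(1i * phase)
    z <- Re(fft(spec, inverse = TRUE)) / (n * n)
    z <- (z - min(z)) / diff(range(z)) * 2 * relief_amplitude_m -
      relief_amplitude_m
  } else {
    z <- matrix(0, n, n)
  }
  elev <- base_elevation_m + z
  slope <- slope_from_dem(elev, coarse_res)
  twi <- twi_from_dem(elev, slope, coarse_res, twi_range)
  water <- matrix(FALSE, n, n)
  if (water_fraction > 0) {
    k_water <- max(0L, round(water_fraction * n * n))
    if (k_water > 0)
      water[order(elev)[seq_len(k_water)]] <- TRUE
  }
  new_landscape(elev, slope, twi, water, coarse_res = coarse_res,
                fine_res = fine_res, litter_init = litter_init,
                active_init = active_init)
}

# slope in degrees from central differences (one-sided at edges)
slope_from_dem <- function(elev, res) {
  n <- nrow(elev); m <- ncol(elev)
  pad <- function(i, k) pmin(pmax(i, 1L), k)
  dzdx <- (elev[, pad(2:(m + 1), m)] - elev[, pad(0:(m - 1), m)]) /
    ((pad(2:(m + 1), m) - pad(0:(m - 1), m))[col(elev)] * res)
  dzdy <- (elev[pad(2:(n + 1), n), ] - elev[pad(0:(n - 1), n), ]) /
    ((pad(2:(n + 1), n) - pad(0:(n - 1), n))[row(elev)] * res)
  atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
}

# TWI = ln(contributing area / tan(slope)), single-flow-direction (D8)
# accumulation: each cell passes its accumulated area to its steepest
# strictly-lower 8-neighbor.
twi_from_dem <- function(elev, slope, res, twi_range = NULL) {
  n <- nrow(elev); m <- ncol(elev)
  acc <- matrix(1, n, n)                 # in units of cell area
  ord <- order(elev, decreasing = TRUE)
  nbr_dr <- c(-1, -1, -1, 0, 0, 1, 1, 1)
  nbr_dc <- c(-1, 0, 1, -1, 1, -1, 0, 1)
  nbr_dist <- sqrt(nbr_dr^2 + nbr_dc^2)
  for (idx in ord) {
    r <- ((idx - 1L) %% n) + 1L
    cc <- ((idx - 1L) %/% n) + 1L
    best <- 0; bi <- 0L
    for (k in 1:8) {
      rr <- r + nbr_dr[k]; c2 <- cc + nbr_dc[k]
      if (rr < 1L || rr > n || c2 < 1L || c2 > m) next
      drop <- (elev[r, cc] - elev[rr, c2]) / nbr_dist[k]
      if (drop > best) { best <- drop; bi <- (c2 - 1L) * n + rr }
    }
    if (bi > 0L) acc[bi] <- acc[bi] + acc[idx]
  }
  tanb <- pmax(tan(slope * pi / 180), tan(0.05 * pi / 180))
  twi <- log(acc * res * res / tanb)
  if (!is.null(twi_range)) {
    rng <- range(twi)
    if (diff(rng) > 0) {
      twi <- twi_range[1] + (twi - rng[1]) / diff(rng) * diff(twi_range)
    } else {
      twi[] <- twi_range[2]              # flat terrain: uniformly wettest
    }
  }
  twi
}
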