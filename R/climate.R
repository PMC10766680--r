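#' Reference monthly climatology for the Central Yakutian study region
#'
#' Monthly mean temperature (deg C) and precipitation sum (mm) used as
#' localization targets and as defaults for the synthetic climate generator.
#' The values reproduce the observed station-period climatology near the
#' study site: January and July means of -32.3 and 17.8 deg C, an annual
#' precipitation sum of 303 mm with 15 mm in January and 56 mm in July, and
#' June-August carrying 47% of annual precipitation.
#'
#' @return list with numeric vectors `t_mean` and `p_mean`, each length 12
#'   (January to December).
#' @export
reference_climate <- function() {
  mid <- (-32.3 + 17.8) / 2
  amp <- (17.8 - (-32.3)) / 2
  list(
    t_mean = mid - amp * cos(2 * pi * (0:11) / 12),
    p_mean = c(15, 12, 13, 15, 25, 41.4, 56, 45, 30, 23, 16, 11.6)
  )
}

validate_climate <- function(clim, where = "climate") {
  need <- c("year", "month", "t_mon", "p_mon")
  if (!all(need %in% names(clim)))
    stop_fl("%s must have columns %s", where, paste(need, collapse = ", "))
  if (any(clim$p_mon < 0)) stop_fl("%s: negative precipitation", where)
  tab <- table(clim$year)
  bad <- names(tab)[tab != 12L]
  if (length(bad))
    stop_fl("%s: incomplete year %s (expected 12 months, got %d)",
            where, bad[1], tab[[bad[1]]])
  yrs <- sort(unique(clim$year))
  if (length(yrs) > 1L && any(diff(yrs) != 1L))
    stop_fl("%s: years not contiguous", where)
  ord <- order(clim$year, clim$month)
  clim <- clim[ord, , drop = FALSE]
  if (any(clim$month != rep(1:12, length(yrs))))
    stop_fl("%s: months must be 1..12 within each year", where)
  rownames(clim) <- NULL
  class(clim) <- c("fl_climate", "data.frame")
  clim
}

#' Read a monthly climate series from CSV
#'
#' Expects the canonical header `year,month,t_mon_degC,p_mon_mm` (the short
#' names `t_mon`/`p_mon` are also accepted). The series must contain exactly
#' 12 months for every year and contiguous years.
#'
#' @param path CSV file path.
#' @return a data.frame of class `fl_climate` with columns `year`, `month`,
#'   `t_mon` (deg C), `p_mon` (mm).
#' @seealso [write_climate_csv()], [generate_synthetic_climate()]
#' @export
read_climate_csv <- function(path) {
  raw <- read.csv(path, colClasses = "character", check.names = FALSE)
  names(raw) <- sub("^t_mon_degC$", "t_mon", names(raw))
  names(raw) <- sub("^p_mon_mm$", "p_mon", names(raw))
  need <- c("year", "month", "t_mon", "p_mon")
  if (!all(need %in% names(raw)))
    stop_fl("climate CSV %s: expected columns year,month,t_mon_degC,p_mon_mm",
            path)
  num <- lapply(raw[need], function(col) suppressWarnings(as.numeric(col)))
  for (nm in need) {
    bad <- which(is.na(num[[nm]]) & !is.na(raw[[nm]]) & nzchar(raw[[nm]]))
    bad <- c(bad, which(is.na(raw[[nm]]) | !nzchar(raw[[nm]])))
    if (length(bad))
      stop_fl("climate CSV %s: non-numeric value in column '%s', row %d",
              path, nm, min(bad) + 1L)  # +1 for the header line
  }
  validate_climate(as.data.frame(num), where = basename(path))
}

#' @rdname read_climate_csv
#' @param clim an `fl_climate` data.frame.
#' @export
write_climate_csv <- function(clim, path) {
  clim <- validate_climate(as.data.frame(clim))
  out <- data.frame(year = clim$year, month = clim$month,
                    t_mon_degC = clim$t_mon, p_mon_mm = clim$p_mon)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Generate a synthetic monthly climate series
#'
#' Temperature follows a sinusoidal seasonal cycle anchored at the January
#' and July means, plus an AR(1) monthly noise term and an optional linear
#' trend. Monthly precipitation is gamma-distributed around seasonal monthly
#' means (coefficient of variation `p_cv`; `p_cv = 0` gives the deterministic
#' means). Defaults emulate the highly continental climate of Central
#' Yakutia; see [reference_climate()].
#'
#' @param n_years number of years (>= 1).
#' @param start_year first calendar year.
#' @param t_jan,t_jul January and July mean temperatures, deg C.
#' @param p_mean monthly precipitation means, mm (length 12).
#' @param t_noise_sd innovation s.d. of the AR(1) temperature noise, deg C.
#' @param t_ar1 AR(1) coefficient of the temperature noise.
#' @param p_cv coefficient of variation of monthly precipitation.
#' @param t_trend temperature trend, deg C per year (applied linearly).
#' @param seed optional integer seed; same seed gives an identical series.
#' @return an `fl_climate` data.frame.
#' @export
generate_synthetic_climate <- function(n_years, start_year = 1L,
                                       t_jan = -32.3, t_jul = 17.8,
                                       p_mean = reference_climate()$p_mean,
                                       t_noise_sd = 1.5, t_ar1 = 0.3,
                                       p_cv = 0.45, t_trend = 0,
                                       seed = NULL) {
  stopifnot(n_years >= 1, length(p_mean) == 12L)
  if (!is.null(seed)) set.seed(seed)
  n <- n_years * 12L
  month <- rep(1:12, n_years)
  year <- rep(seq.int(start_year, length.out = n_years), each = 12L)
  mid <- (t_jan + t_jul) / 2
  amp <- (t_jul - t_jan) / 2
  seasonal <- mid - amp * cos(2 * pi * (month - 1) / 12)
  noise <- numeric(n)
  if (t_noise_sd > 0) {
    innov <- rnorm(n, 0, t_noise_sd)
    noise <- as.numeric(filter(innov, t_ar1, method = "recursive"))
  }
  trend <- t_trend * (rep(seq_len(n_years), each = 12L) - 1L)
  t_mon <- seasonal + noise + trend
  pm <- p_mean[month]
  if (p_cv > 0) {
    shape <- 1 / p_cv^2
    p_mon <- rgamma(n, shape = shape, scale = pm / shape)
  } else {
    p_mon <- pm
  }
  validate_climate(data.frame(year = year, month = month,
                              t_mon = t_mon, p_mon = p_mon))
}

#' Localize a climate series by fitting monthly means to a reference
#'
#' Bias-corrects a forcing series against a reference climatology over a
#' fitting window: temperature additively, precipitation multiplicatively
#' (standard delta/scaling convention). After localization the mean of each
#' calendar month over the fitting window equals the reference mean.
#'
#' @param clim an `fl_climate` data.frame.
#' @param ref_t,ref_p reference monthly means (length 12), deg C and mm;
#'   default the study-region climatology of [reference_climate()].
#' @param fit_window integer vector of years (range used); defaults to all
#'   years in `clim`.
#' @return the adjusted `fl_climate`.
#' @export
localize_climate <- function(clim, ref_t = reference_climate()$t_mean,
                             ref_p = reference_climate()$p_mean,
                             fit_window = NULL) {
  clim <- validate_climate(as.data.frame(clim))
  stopifnot(length(ref_t) == 12L, length(ref_p) == 12L)
  yrs <- sort(unique(clim$year))
  if (is.null(fit_window)) fit_window <- yrs
  fit_window <- seq.int(min(fit_window), max(fit_window))
  if (!all(fit_window %in% yrs))
    stop_fl("fit_window years %s not in series",
            paste(setdiff(fit_window, yrs), collapse = ","))
  inwin <- clim$year %in% fit_window
  t_src <- tapply(clim$t_mon[inwin], clim$month[inwin], mean)
  p_src <- tapply(clim$p_mon[inwin], clim$month[inwin], mean)
  if (any(p_src == 0 & ref_p > 0))
    stop_fl("zero monthly precipitation mean in source over fitting window; multiplicative factor undefined (month %d)",
            which(p_src == 0 & ref_p > 0)[1])
  p_fac <- as.numeric(ifelse(p_src > 0, ref_p / p_src, 1))
  t_adj <- as.numeric(ref_t - t_src)
  clim$t_mon <- clim$t_mon + t_adj[clim$month]
  clim$p_mon <- pmax(0, clim$p_mon * p_fac[clim$month])
  clim
}

#' Annual climate summaries used by the simulator
#'
#' `growing_season_temp` is the mean temperature over months above 0 deg C
#' (NA if none); `thaw_index` is a degree-day proxy, the sum over months of
#' `max(t_mon, 0) * 30.4` (deg C days), driving the Stefan-type active-layer
#' equilibrium.
#'
#' @param clim an `fl_climate` data.frame.
#' @return named numeric vector, one value per year.
#' @export
growing_season_temp <- function(clim) {
  vapply(split(clim$t_mon, clim$year), function(t) {
    t <- t[t > 0]
    if (!length(t)) NA_real_ else mean(t)
  }, numeric(1))
}

#' @rdname growing_season_temp
#' @export
thaw_index <- function(clim) {
  vapply(split(clim$t_mon, clim$year),
         function(t) sum(pmax(t, 0)) * 30.4, numeric(1))
}
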