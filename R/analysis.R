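#' Composite forest-structure metrics
#'
#' Thresholds follow the standard output definitions of the study system:
#' the stem count includes all live trees at least 130 cm tall; seedlings
#' are trees of 0 to 40 cm; mean mature height averages trees above 200 cm;
#' the evergreen to deciduous ratio is reported as missing when no
#' deciduous tree is alive. Trees of 40-130 cm belong to neither the stem
#' nor the seedling class.
#'
#' @param trees an `fl_trees` data.frame.
#' @param traits species trait table.
#' @return list with `stem_count`, `stems_per_species`, `seedling_count`,
#'   `mean_height_mature`, `evergreen_deciduous_ratio`, `n_live`.
#' @export
structure_metrics <- function(trees, traits) {
  live <- trees$alive
  h <- trees$height[live]
  sp <- trees$species[live]
  stems <- h >= 130
  mature <- h > 200
  everg <- !traits$deciduous[sp]
  n_dec <- sum(!everg)
  list(stem_count = sum(stems),
       stems_per_species = tabulate(sp[stems], nbins = nrow(traits)),
       seedling_count = sum(h >= 0 & h <= 40),
       mean_height_mature = if (any(mature)) mean(h[mature]) else NA_real_,
       evergreen_deciduous_ratio = if (n_dec > 0) sum(everg) / n_dec
       else NA_real_,
       n_live = sum(live))
}

#' Superposed epoch analysis of a disturbance response
#'
#' Cuts a fixed window (default 10 years pre- to 30 years post-fire) out of
#' an annual series around every fire year, superimposes the windows, and
#' summarizes the response at each relative year by the across-event median
#' and a quantile band. Windows truncated by the series edges are dropped
#' (and counted); overlapping windows from fires closer than the window
#' length are all kept.
#'
#' @param series annual values: either a numeric vector with `years`, or a
#'   data.frame with columns `year` and `value` (or a second column).
#' @param fire_years years of fire occurrence.
#' @param pre,post window half-widths in years.
#' @param quantiles lower and upper band quantiles (default quartiles).
#' @param years years matching `series` when it is a bare vector.
#' @return data.frame of class `fl_sea` with columns `rel_year` (-pre..
#'   post), `median`, `q_lo`, `q_hi`, and attributes `n_events`,
#'   `n_dropped`.
#' @export
superposed_epoch <- function(series, fire_years, pre = 10, post = 30,
                             quantiles = c(0.25, 0.75), years = NULL) {
  if (is.data.frame(series)) {
    years <- series$year
    vcol <- if ("value" %in% names(series)) "value" else names(series)[2]
    values <- series[[vcol]]
  } else {
    values <- as.numeric(series)
    if (is.null(years)) years <- seq_along(values)
  }
  stopifnot(length(values) == length(years))
  rel <- seq.int(-pre, post)
  win <- lapply(fire_years, function(fy) {
    pos <- match(fy + rel, years)
    if (anyNA(pos)) NULL else values[pos]
  })
  dropped <- sum(vapply(win, is.null, TRUE))
  win <- win[!vapply(win, is.null, TRUE)]
  if (!length(win)) stop_fl("no usable fire windows inside the series")
  m <- do.call(rbind, win)
  out <- data.frame(rel_year = rel,
                    median = apply(m, 2L, median),
                    q_lo = apply(m, 2L, quantile, probs = quantiles[1]),
                    q_hi = apply(m, 2L, quantile, probs = quantiles[2]))
  attr(out, "n_events") <- length(win)
  attr(out, "n_dropped") <- dropped
  class(out) <- c("fl_sea", "data.frame")
  out
}

#' Post-fire recovery time from a superposed epoch analysis
#'
#' The pre-fire baseline is the mean of the SEA median over relative years
#' `-pre .. -1`; recovery time is the smallest post-fire relative year (1
#' to the window end) at which the median again reaches the baseline, or
#' missing (`NA`) if it never does within the window. A flat response
#' recovers at year +1.
#'
#' @param sea an [superposed_epoch()] result.
#' @return list with `recovery_yr` (integer or `NA`) and `baseline`.
#' @export
recovery_time <- function(sea) {
  pre <- sea$rel_year < 0
  baseline <- mean(sea$median[pre])
  post <- sea$rel_year >= 1
  hit <- which(sea$median[post] >= baseline)
  list(recovery_yr = if (length(hit)) sea$rel_year[post][min(hit)]
       else NA_integer_,
       baseline = baseline)
}

#' Superposed epoch analysis straight from run output files
#'
#' Convenience wrapper matching the run output schema: reads `annual.csv`
#' and `fires.csv`, runs [superposed_epoch()] on the total stem count, and
#' optionally writes `rel_year,median,q_lo,q_hi,n_events` CSV.
#'
#' @param annual_csv,fires_csv run output files.
#' @param out optional output CSV path.
#' @param column column of the annual table to analyze.
#' @inheritParams superposed_epoch
#' @return the `fl_sea` data.frame, invisibly if `out` is given.
#' @export
sea_from_files <- function(annual_csv, fires_csv, out = NULL,
                           column = "stem_count", pre = 10, post = 30,
                           quantiles = c(0.25, 0.75)) {
  annual <- read.csv(annual_csv)
  fires <- read.csv(fires_csv)
  sea <- superposed_epoch(annual[[column]], fires$year, pre = pre,
                          post = post, quantiles = quantiles,
                          years = annual$year)
  if (!is.null(out)) {
    df <- as.data.frame(sea)
    df$n_events <- attr(sea, "n_events")
    write.csv(df, out, row.names = FALSE, quote = FALSE)
    return(invisible(sea))
  }
  sea
}
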