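#' Monthly fire probability rating model
#'
#' The monthly fire probability rating (FPR_mon) is a linear model of
#' monthly mean temperature and precipitation sum, applied only to months
#' above 0 deg C. Categorization thresholds follow the published rating
#' quantiles: ratings below 6.6 carry no fire weather, `[6.6, 7.0)` is mild,
#' `[7.0, 7.46)` severe, and `>= 7.46` extreme (boundaries belong to the
#' higher class). The default coefficients are a documented
#' parameterization, warmer/drier months rate higher, chosen so that a warm
#' dry month (20 deg C, 20 mm) rates near the extreme threshold; they are
#' fully configurable (see `inst/extdata/fpr_model.yaml`) and can be refit
#' to observed fire counts with [refit_fpr_model()].
#'
#' @param intercept,coef_t,coef_p linear-model coefficients (per deg C, per
#'   mm).
#' @param threshold_min,threshold_severe,threshold_extreme category
#'   thresholds.
#' @return an object of class `fl_fpr_model`.
#' @export
fpr_model <- function(intercept = 6.2, coef_t = 0.08, coef_p = -0.01,
                      threshold_min = 6.6, threshold_severe = 7.0,
                      threshold_extreme = 7.46) {
  if (!(threshold_min < threshold_severe && threshold_severe < threshold_extreme))
    stop_fl("thresholds must satisfy min < severe < extreme")
  structure(list(intercept = intercept, coef_t = coef_t, coef_p = coef_p,
                 threshold_min = threshold_min,
                 threshold_severe = threshold_severe,
                 threshold_extreme = threshold_extreme),
            class = "fl_fpr_model")
}

#' @export
print.fl_fpr_model <- function(x, ...) {
  cat(sprintf("<fl_fpr_model> rating = %.3g + %.3g T %+.3g P (months with T > 0 degC)\n",
              x$intercept, x$coef_t, x$coef_p))
  cat(sprintf("  thresholds: mild %.3g, severe %.3g, extreme %.3g\n",
              x$threshold_min, x$threshold_severe, x$threshold_extreme))
  invisible(x)
}

#' Monthly fire probability rating
#'
#' @param t monthly mean temperature, deg C (vectorized).
#' @param p monthly precipitation sum, mm.
#' @param model an [fpr_model()].
#' @return numeric rating; `NA` for months at or below 0 deg C (no rating is
#'   assigned to frozen months).
#' @export
fpr_mon <- function(t, p, model = fpr_model()) {
  r <- model$intercept + model$coef_t * t + model$coef_p * p
  r[t <= 0] <- NA_real_
  r
}

#' Categorize a monthly rating into fire-weather classes
#'
#' @param rating numeric rating (possibly `NA` for unrated months).
#' @param model an [fpr_model()].
#' @return factor with levels `none`, `mild`, `severe`, `extreme`.
#' @export
fpr_categorize <- function(rating, model = fpr_model()) {
  out <- cut(rating,
             breaks = c(-Inf, model$threshold_min, model$threshold_severe,
                        model$threshold_extreme, Inf),
             labels = c("none", "mild", "severe", "extreme"),
             right = FALSE)
  out[is.na(rating)] <- "none"
  out
}

#' Calibration of the annual fire probability rating
#'
#' FPR_ann aggregates the year's category counts as a clamped weighted sum,
#' `min(1, max(0, scale * (w_mild n_mild + w_severe n_severe + w_extreme
#' n_extreme)))`. Weights default to (1, 2, 4); `scale` is fitted by
#' [calibrate_fpr()] so that the mean FPR_ann over a climate series equals
#' `target_mean` (default 0.03, i.e. on average one fire per c. 33 years).
#'
#' @param scale positive scale applied to the weighted category count.
#' @param weights length-3 non-negative weights for (mild, severe, extreme).
#' @param target_mean target mean annual ignition probability.
#' @return an object of class `fl_fpr_calibration`.
#' @export
fpr_calibration <- function(scale = 0.0075, weights = c(1, 2, 4),
                            target_mean = 0.03) {
  stopifnot(scale > 0, length(weights) == 3L, all(weights >= 0))
  structure(list(scale = scale, weights = weights, target_mean = target_mean),
            class = "fl_fpr_calibration")
}

#' Annual fire probability rating from 12 months of climate
#'
#' Rates and categorizes each month, counts mild/severe/extreme fire
#' weather, and aggregates to the annual ignition probability FPR_ann in
#' `[0, 1]`.
#'
#' @param months an `fl_climate` data.frame with exactly 12 rows of one
#'   year.
#' @param model an [fpr_model()].
#' @param cal an [fpr_calibration()].
#' @return list with `year`, `n_mild`, `n_severe`, `n_extreme`, `fpr_ann`.
#' @export
annual_rating <- function(months, model = fpr_model(),
                          cal = fpr_calibration()) {
  if (nrow(months) != 12L || length(unique(months$year)) != 1L)
    stop_fl("annual_rating needs exactly 12 months of one year")
  cat_ <- fpr_categorize(fpr_mon(months$t_mon, months$p_mon, model), model)
  n <- tabulate(cat_, nbins = 4L)
  list(year = months$year[1], n_mild = n[2], n_severe = n[3],
       n_extreme = n[4],
       fpr_ann = fpr_ann_from_counts(n[2], n[3], n[4], cal))
}

#' @rdname annual_rating
#' @param n_mild,n_severe,n_extreme category counts (vectorized).
#' @export
fpr_ann_from_counts <- function(n_mild, n_severe, n_extreme,
                                cal = fpr_calibration()) {
  w <- cal$weights
  clamp(cal$scale * (w[1] * n_mild + w[2] * n_severe + w[3] * n_extreme),
        0, 1)
}

#' Annual ratings for a multi-year climate series
#'
#' @inheritParams annual_rating
#' @param clim an `fl_climate` data.frame.
#' @return data.frame with one row per year: `year`, `n_mild`, `n_severe`,
#'   `n_extreme`, `fpr_ann`.
#' @export
fpr_series <- function(clim, model = fpr_model(), cal = fpr_calibration()) {
  clim <- validate_climate(as.data.frame(clim))
  cat_ <- fpr_categorize(fpr_mon(clim$t_mon, clim$p_mon, model), model)
  counts <- t(vapply(split(as.integer(cat_), clim$year),
                     tabulate, integer(4L), nbins = 4L))
  yrs <- as.integer(rownames(counts))
  ord <- order(yrs)
  data.frame(year = yrs[ord], n_mild = counts[ord, 2],
             n_severe = counts[ord, 3], n_extreme = counts[ord, 4],
             fpr_ann = fpr_ann_from_counts(counts[ord, 2], counts[ord, 3],
                                           counts[ord, 4], cal))
}

#' Calibrate the annual rating scale to a target mean ignition probability
#'
#' Fixes the category weights and solves for `scale` by monotone bisection
#' so that the mean FPR_ann over the series equals `target_mean` (to 1e-6 or
#' better). Because FPR_ann is clamped at 1, very high targets can be
#' unattainable; in that case the achievable maximum is reported in the
#' error.
#'
#' @inheritParams fpr_series
#' @param target_mean target mean FPR_ann over the series.
#' @param weights length-3 category weights (mild, severe, extreme).
#' @param tol convergence tolerance on the achieved mean.
#' @return an [fpr_calibration()] whose `scale` achieves the target.
#' @export
calibrate_fpr <- function(clim, model = fpr_model(), target_mean = 0.03,
                          weights = c(1, 2, 4), tol = 1e-9) {
  fs <- fpr_series(clim, model, fpr_calibration(scale = 1, weights = weights))
  w <- weights[1] * fs$n_mild + weights[2] * fs$n_severe +
    weights[3] * fs$n_extreme
  if (all(w == 0)) stop_fl("no fire weather in series")
  achieved <- function(s) mean(clamp(s * w, 0, 1))
  max_attainable <- mean(w > 0)
  if (target_mean > max_attainable + tol)
    stop_fl("target mean %.4g unattainable; achievable maximum is %.4g",
            target_mean, max_attainable)
  lo <- 0; hi <- target_mean / mean(w)      # exact when nothing clamps
  while (achieved(hi) < target_mean - tol) hi <- hi * 2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (achieved(mid) < target_mean) lo <- mid else hi <- mid
    if (abs(achieved(mid) - target_mean) < tol) break
  }
  fpr_calibration(scale = (lo + hi) / 2, weights = weights,
                  target_mean = target_mean)
}

#' Refit the monthly rating model to observed fire counts
#'
#' Ordinary least squares of `log1p(fire count)` on monthly temperature and
#' precipitation over months above 0 deg C (fire counts are heavily
#' zero-inflated; only the fitted rating's quantiles matter downstream, so
#' any monotone transform is admissible). Thresholds are recomputed from the
#' fitted ratings: the minimum threshold as the highest rating among
#' zero-fire months, the severe threshold as the third quartile of ratings
#' above the minimum, and the extreme threshold as their maximum.
#'
#' @param fire_counts non-negative monthly fire counts aligned with `clim`.
#' @param clim an `fl_climate` data.frame (same number of rows).
#' @return list with `model` (an [fpr_model()]), `fit` (the `lm` object),
#'   and `r_squared`.
#' @export
refit_fpr_model <- function(fire_counts, clim) {
  clim <- validate_climate(as.data.frame(clim))
  if (length(fire_counts) != nrow(clim))
    stop_fl("fire_counts must align with the climate series")
  if (any(fire_counts < 0)) stop_fl("fire_counts must be >= 0")
  use <- clim$t_mon > 0
  if (sum(use) < 3L) stop_fl("fewer than 3 usable months (T > 0 degC)")
  d <- data.frame(y = log1p(fire_counts[use]), t = clim$t_mon[use],
                  p = clim$p_mon[use])
  if (var(d$t) == 0 || var(d$p) == 0)
    stop_fl("zero-variance climate: singular design")
  fit <- lm(y ~ t + p, data = d)
  cf <- coef(fit)
  rating <- as.numeric(fitted(fit))
  zero_fire <- fire_counts[use] == 0
  thr_min <- if (any(zero_fire)) max(rating[zero_fire]) else
    unname(quantile(rating, 0.25))
  above <- rating[rating >= thr_min]
  if (length(above) < 2L) above <- rating
  thr_sev <- unname(quantile(above, 0.75))
  thr_ext <- max(above)
  eps <- max(1e-8, 1e-6 * abs(thr_ext))
  if (thr_sev <= thr_min) thr_sev <- thr_min + eps
  if (thr_ext <= thr_sev) thr_ext <- thr_sev + eps
  list(model = fpr_model(intercept = unname(cf[1]), coef_t = unname(cf[2]),
                         coef_p = unname(cf[3]), threshold_min = thr_min,
                         threshold_severe = thr_sev,
                         threshold_extreme = thr_ext),
       fit = fit, r_squared = summary(fit)$r.squared)
}

#' Read or write rating-model parameters as YAML
#'
#' File layout: top-level keys `fpr_model` (intercept, coef_t, coef_p,
#' thresholds) and `fpr_calibration` (weights, scale, target_mean).
#'
#' @param path YAML file path.
#' @return `read_fpr_yaml`: list with elements `model` and `calibration`.
#' @export
read_fpr_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  m <- y$fpr_model %||% list()
  cl <- y$fpr_calibration %||% list()
  list(model = do.call(fpr_model, m),
       calibration = do.call(fpr_calibration,
                             cl[names(cl) %in%
                                  c("scale", "weights", "target_mean")]))
}

#' @rdname read_fpr_yaml
#' @param model an [fpr_model()].
#' @param cal an [fpr_calibration()].
#' @export
write_fpr_yaml <- function(model, cal, path) {
  yaml::write_yaml(list(fpr_model = unclass(model),
                        fpr_calibration = unclass(cal)), path)
  invisible(path)
}
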