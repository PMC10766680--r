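test_that("frozen months carry no rating; the linear model behaves as stated", {
  expect_true(is.na(fpr_mon(-5, 30)))
  expect_true(is.na(fpr_mon(0, 30)))
  m0 <- fpr_model(intercept = 7, coef_t = 0, coef_p = 0)
  expect_equal(fpr_mon(10, 30, m0), 7)
  # warmer/drier months always rate higher under the default model
  grid <- expand.grid(t = seq(1, 25, by = 2), p = seq(0, 120, by = 10))
  r <- fpr_mon(grid$t, grid$p)
  for (p in unique(grid$p))
    expect_true(all(diff(r[grid$p == p][order(grid$t[grid$p == p])]) > 0))
  for (t in unique(grid$t))
    expect_true(all(diff(r[grid$t == t][order(grid$p[grid$t == t])]) < 0))
})

test_that("category thresholds partition the rating line", {
  expect_equal(as.character(fpr_categorize(6.5)), "none")
  expect_equal(as.character(fpr_categorize(6.6)), "mild")
  expect_equal(as.character(fpr_categorize(7.2)), "severe")
  expect_equal(as.character(fpr_categorize(7.46)), "extreme")
  ratings <- seq(5, 9, by = 0.01)
  cats <- fpr_categorize(ratings)
  expect_false(anyNA(cats))                      # exactly one class each
  expect_true(all(diff(as.integer(cats)) >= 0))  # classes ordered in rating
})

test_that("annual rating counts categories and clamps to [0, 1]", {
  clim <- generate_synthetic_climate(1, seed = 1)
  frozen <- clim
  frozen$t_mon <- -10
  ar <- annual_rating(frozen)
  expect_equal(c(ar$n_mild, ar$n_severe, ar$n_extreme), c(0L, 0L, 0L))
  expect_equal(ar$fpr_ann, 0)

  big <- fpr_calibration(scale = 10)
  expect_equal(fpr_ann_from_counts(0, 0, 12, big), 1)   # clamped
  expect_error(annual_rating(clim[1:11, ]), "12 months")
})

test_that("FPR_ann is bounded and monotone over all category-count triples", {
  cal <- fpr_calibration(scale = 0.02)
  triples <- expand.grid(m = 0:12, s = 0:12, e = 0:12)
  triples <- triples[rowSums(triples) <= 12, ]
  expect_equal(nrow(triples), 455L)
  f <- fpr_ann_from_counts(triples$m, triples$s, triples$e, cal)
  expect_true(all(f >= 0 & f <= 1))
  # promoting any month's category never decreases the annual rating
  promote_ms <- fpr_ann_from_counts(triples$m - 1, triples$s + 1, triples$e,
                                    cal)[triples$m > 0]
  expect_true(all(promote_ms >= f[triples$m > 0]))
  promote_se <- fpr_ann_from_counts(triples$m, triples$s - 1, triples$e + 1,
                                    cal)[triples$s > 0]
  expect_true(all(promote_se >= f[triples$s > 0]))
  promote_nm <- fpr_ann_from_counts(triples$m + 1, triples$s, triples$e,
                                    cal)[rowSums(triples) < 12]
  expect_true(all(promote_nm >= f[rowSums(triples) < 12]))
})

test_that("calibration solves the scale exactly and linearly when nothing clamps", {
  # identical years each contributing weighted count 4 -> closed form
  clim <- generate_synthetic_climate(5, t_noise_sd = 0, p_cv = 0, seed = 1)
  fs <- fpr_series(clim, cal = fpr_calibration(scale = 1))
  w <- fs$n_mild + 2 * fs$n_severe + 4 * fs$n_extreme
  expect_true(all(w == w[1]) && w[1] > 0)
  cal <- calibrate_fpr(clim, target_mean = 0.03)
  expect_equal(cal$scale, 0.03 / w[1], tolerance = 1e-6)

  cal2 <- calibrate_fpr(clim, target_mean = 0.06)
  expect_equal(cal2$scale / cal$scale, 2, tolerance = 1e-5)

  frozen <- clim
  frozen$t_mon <- -5
  expect_error(calibrate_fpr(frozen), "no fire weather")
})

test_that("calibration closes the loop on a noisy series to 1e-6", {
  clim <- generate_synthetic_climate(1000, seed = 17)
  cal <- calibrate_fpr(clim, target_mean = 0.03)
  achieved <- mean(fpr_series(clim, cal = cal)$fpr_ann)
  expect_lt(abs(achieved - 0.03), 1e-6)
})

test_that("warming a single month never lowers the annual rating", {
  clim <- generate_synthetic_climate(1, seed = 21)
  cal <- fpr_calibration(scale = 0.01)
  base <- annual_rating(clim, cal = cal)$fpr_ann
  for (m in 1:12) {
    warm <- clim
    warm$t_mon[m] <- warm$t_mon[m] + 6
    expect_gte(annual_rating(warm, cal = cal)$fpr_ann, base)
  }
})

test_that("refitting recovers known coefficients from noisy fire counts", {
  set.seed(31)
  clim <- generate_synthetic_climate(60, seed = 31)
  use <- clim$t_mon > 0
  truth <- c(a = 0.6, bt = 0.08, bp = -0.002)
  lin <- truth["a"] + truth["bt"] * clim$t_mon + truth["bp"] * clim$p_mon
  counts <- numeric(nrow(clim))
  counts[use] <- expm1(pmax(0, lin[use] + rnorm(sum(use), 0, 0.15)))
  fit <- refit_fpr_model(counts, clim)
  se <- coef(summary(fit$fit))[, "Std. Error"]
  expect_lt(abs(coef(fit$fit)["t"] - truth["bt"]), 2 * se["t"])
  expect_lt(abs(coef(fit$fit)["p"] - truth["bp"]), 2 * se["p"])

  flatclim <- clim
  flatclim$t_mon <- 10
  flatclim$p_mon <- 30
  expect_error(refit_fpr_model(counts, flatclim), "singular")
  expect_error(refit_fpr_model(counts[1:10], clim), "align")
})

test_that("refitted thresholds reproduce the rating sample's quartiles", {
  set.seed(33)
  clim <- generate_synthetic_climate(40, seed = 33)
  use <- clim$t_mon > 0
  # a steeper model with frequent zero-fire months exercises every branch
  lin <- -1 + 0.15 * clim$t_mon - 0.01 * clim$p_mon
  counts <- numeric(nrow(clim))
  counts[use] <- expm1(pmax(0, lin[use] + rnorm(sum(use), 0, 0.3)))
  expect_gt(sum(counts[use] == 0), 3)
  fit <- refit_fpr_model(counts, clim)
  rating <- as.numeric(fitted(fit$fit))
  zero <- counts[use] == 0
  thr_min <- max(rating[zero])
  above <- rating[rating >= thr_min]
  expect_equal(fit$model$threshold_min, thr_min)
  expect_equal(fit$model$threshold_severe, unname(quantile(above, 0.75)))
  expect_equal(fit$model$threshold_extreme, max(above))
})

test_that("rating model and calibration round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_fpr_yaml(fpr_model(coef_t = 0.09), fpr_calibration(scale = 0.005),
                 path)
  back <- read_fpr_yaml(path)
  expect_equal(back$model$coef_t, 0.09)
  expect_equal(back$calibration$scale, 0.005)
})
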