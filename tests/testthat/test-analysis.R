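traits <- species_defaults()

test_that("structure metrics apply the size thresholds exactly", {
  tr <- make_stand(3, heights = c(129.9, 130.0, 250))
  m <- structure_metrics(tr, traits)
  expect_equal(m$stem_count, 2L)                 # 129.9 excluded, 130 included
  tr2 <- make_stand(3, heights = c(50, 250, 350))
  m2 <- structure_metrics(tr2, traits)
  expect_equal(m2$mean_height_mature, 300)
  expect_equal(m2$seedling_count, 0L)
  tr3 <- make_stand(4, heights = c(10, 40, 40.1, 90))
  expect_equal(structure_metrics(tr3, traits)$seedling_count, 2L)
  # stems + seedlings never exceed the live total (40-130 cm is neither)
  set.seed(1)
  tr4 <- make_stand(200)
  m4 <- structure_metrics(tr4, traits)
  expect_lte(m4$stem_count + m4$seedling_count, m4$n_live)
})

test_that("the evergreen-deciduous ratio handles pure stands", {
  larch <- make_stand(5, species = 1L)
  expect_equal(structure_metrics(larch, traits)$evergreen_deciduous_ratio, 0)
  pine <- make_stand(5, species = 5L)
  expect_true(is.na(structure_metrics(pine, traits)$evergreen_deciduous_ratio))
})

test_that("superposed epochs reproduce constant and two-event arithmetic", {
  sea <- superposed_epoch(rep(42, 100), fire_years = 50)
  expect_true(all(sea$median == 42))
  expect_equal(sea$rel_year, -10:30)

  x <- rep(2, 120)
  x[61:120] <- 4
  sea2 <- superposed_epoch(x, fire_years = c(30, 90))
  expect_true(all(sea2$median == 3))             # median of {2, 4}
  expect_equal(attr(sea2, "n_events"), 2L)
})

test_that("truncated windows are dropped and counted", {
  sea <- superposed_epoch(seq_len(100), fire_years = c(5, 50, 98))
  expect_equal(attr(sea, "n_events"), 1L)
  expect_equal(attr(sea, "n_dropped"), 2L)
  expect_error(superposed_epoch(seq_len(20), fire_years = 5), "no usable")
})

test_that("a constructed step response is recovered by superposition", {
  # 100 events with a drop of d at +0 and linear recovery over 20 years
  set.seed(2)
  base <- 100
  n_ev <- 100
  series <- rep(base, 6000)
  fire_years <- sort(sample(seq(20, 5950, by = 55), n_ev))
  for (fy in fire_years) {
    rec <- base - 40 * pmax(0, 1 - (0:30) / 20)
    series[fy:(fy + 30)] <- rec
  }
  sea <- superposed_epoch(series, fire_years)
  expect_equal(sea$median[sea$rel_year == 0], 60)
  expect_equal(sea$median[sea$rel_year == 10], 80)
  expect_equal(sea$median[sea$rel_year >= 20],
               rep(100, 11))
  rt <- recovery_time(sea)
  expect_equal(rt$recovery_yr, 20L)
})

test_that("superposition is order-invariant and homogeneous of degree one", {
  set.seed(3)
  series <- 100 + cumsum(rnorm(500))
  fy <- c(60, 200, 340, 450)
  a <- superposed_epoch(series, fy)
  b <- superposed_epoch(series, rev(fy))
  expect_equal(a, b)
  c2 <- superposed_epoch(2.5 * series, fy)
  expect_equal(c2$median, 2.5 * a$median)
  expect_equal(c2$q_lo, 2.5 * a$q_lo)
})

test_that("recovery time hits its boundary cases", {
  flat <- superposed_epoch(rep(7, 100), fire_years = 50)
  expect_equal(recovery_time(flat)$recovery_yr, 1L)

  # a collapse that never returns within the window stays missing
  x <- rep(100, 200)
  x[100:200] <- 10
  sank <- superposed_epoch(x, fire_years = 100)
  expect_true(is.na(recovery_time(sank)$recovery_yr))

  # linear recovery crossing the baseline at +12
  y <- rep(50, 300)
  y[150:(150 + 30)] <- 50 - 24 + 2 * (0:30)
  sea <- superposed_epoch(y, fire_years = 150)
  expect_equal(recovery_time(sea)$recovery_yr, 12L)
})

test_that("scenario files sort in natural numeric order", {
  x <- c("run_10", "run_2", "run_1", "fixed_fri100_fi0.5", "fixed_fri50_fi1")
  expect_equal(mixed_sort(c("run_10", "run_2", "run_1")),
               c("run_1", "run_2", "run_10"))
  expect_equal(mixed_sort(c("fixed_fri100_fi0.5", "fixed_fri50_fi1"))[1],
               "fixed_fri50_fi1")
  expect_equal(mixed_sort(c("b", "a")), c("a", "b"))
})

test_that("file-based SEA matches the in-memory result", {
  dir <- withr::local_tempdir()
  annual <- data.frame(year = 1:200, stem_count = rep(500, 200))
  annual$stem_count[100:110] <- 100
  fires <- data.frame(year = 100)
  write.csv(annual, file.path(dir, "annual.csv"), row.names = FALSE)
  write.csv(fires, file.path(dir, "fires.csv"), row.names = FALSE)
  sea <- sea_from_files(file.path(dir, "annual.csv"),
                        file.path(dir, "fires.csv"),
                        out = file.path(dir, "sea.csv"))
  ref <- superposed_epoch(annual$stem_count, 100, years = annual$year)
  expect_equal(as.data.frame(sea), as.data.frame(ref))
  back <- read.csv(file.path(dir, "sea.csv"))
  expect_equal(back$median, ref$median)
})
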