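test_that("fire-off runs never burn and reruns are bit-identical", {
  ls <- small_landscape()
  clim <- stationary_climate(40)
  cfg <- run_config(fire_mode = "off", seed = 3, snapshot_every = 0)
  sim1 <- fl_run(fl_simulation(ls, clim, config = cfg))
  res1 <- simulation_results(sim1)
  expect_true(all(res1$annual$burned_cells == 0))
  expect_equal(nrow(res1$fires), 0L)

  sim2 <- fl_run(fl_simulation(ls, clim, config = cfg))
  res2 <- simulation_results(sim2)
  expect_identical(res1$annual, res2$annual)
  expect_identical(sim1$trees, sim2$trees)
})

test_that("fixed mode fires exactly on schedule", {
  ls <- small_landscape()
  clim <- stationary_climate(500)
  cfg <- run_config(fire_mode = "fixed", fixed_fri = 50, fixed_fi = 0.1,
                    seed = 1, snapshot_every = 0)
  res <- simulation_results(fl_run(fl_simulation(ls, clim, config = cfg)))
  expect_equal(nrow(res$fires), 10L)
  expect_equal(res$fires$year, seq(50, 500, by = 50))
  expect_true(all(res$fires$burned_cells == sum(!ls$water_fine)))
})

test_that("fire randomness lives in its own substreams", {
  # demographic draws are untouched by the fire module: an ignition-capable
  # run matches the fire-off run exactly until its first fire year
  ls <- small_landscape()
  clim <- stationary_climate(60)
  cfg_on <- run_config(fire_mode = "fixed", fixed_fri = 30, fixed_fi = 0.8,
                       seed = 11, snapshot_every = 0)
  cfg_off <- run_config(fire_mode = "off", seed = 11, snapshot_every = 0)
  on <- simulation_results(fl_run(fl_simulation(ls, clim, config = cfg_on)))
  off <- simulation_results(fl_run(fl_simulation(ls, clim,
                                                 config = cfg_off)))
  first_fire <- min(on$fires$year)
  pre <- on$annual$year < first_fire
  expect_equal(on$annual[pre, ], off$annual[pre, ])
  expect_false(isTRUE(all.equal(on$annual$stem_count,
                                off$annual$stem_count)))
})

test_that("no tree, seed, or litter ever appears on water", {
  ls <- small_landscape(water_fraction = 0.25)
  clim <- stationary_climate(50)
  cfg <- run_config(fire_mode = "fixed", fixed_fri = 20, fixed_fi = 0.6,
                    seed = 5, snapshot_every = 0)
  sim <- fl_run(fl_simulation(ls, clim, config = cfg))
  cells <- firelarch:::fine_index(ls, sim$trees$x, sim$trees$y)
  expect_false(any(ls$water_fine[cells]))
  expect_true(all(sim$landscape$litter[ls$water_fine] == 0))
  expect_true(all(sim$ground_seeds[ls$water_fine, ] == 0))
})

test_that("tree counts change only through establishment, mortality, and fire", {
  ls <- small_landscape()
  clim <- stationary_climate(30)
  cfg <- run_config(fire_mode = "fixed", fixed_fri = 10, fixed_fi = 0.5,
                    seed = 7, snapshot_every = 0)
  sim <- fl_simulation(ls, clim, config = cfg)
  for (k in 1:30) {
    ids_before <- sim$trees$id[sim$trees$alive]
    run_annual_cycle(sim)
    ids_after <- sim$trees$id[sim$trees$alive]
    # no tree is ever created except by establishment (fresh ids)
    expect_true(all(setdiff(ids_after, ids_before) > max(0, ids_before)))
    # dead trees never return
    expect_true(all(ids_after %in% c(ids_before,
                                     setdiff(ids_after, ids_before))))
  }
})

test_that("snapshots agree with the annual stem count", {
  ls <- small_landscape()
  clim <- stationary_climate(20)
  cfg <- run_config(fire_mode = "off", seed = 9, snapshot_every = 10)
  res <- simulation_results(fl_run(fl_simulation(ls, clim, config = cfg)))
  for (snap in res$snapshots) {
    rec <- res$annual[res$annual$year == snap$year, ]
    expect_equal(sum(snap$stems), rec$stem_count)
  }
})

test_that("with fire off and stationary climate the stand reaches quasi-steady state", {
  # 50 x 50 m stand so demographic noise does not mask the equilibrium
  ls <- generate_synthetic_landscape(2, coarse_res = 25.2, seed = 3)
  clim <- stationary_climate(1000)
  cfg <- run_config(fire_mode = "off", seed = 13, snapshot_every = 0)
  res <- simulation_results(fl_run(fl_simulation(ls, clim, config = cfg)))
  late <- tail(res$annual, 300)
  fit <- lm(stem_count ~ year, data = late)
  drift <- abs(coef(fit)["year"]) * 300 / mean(late$stem_count)
  expect_lt(drift, 0.2)    # trend indistinguishable from flat at this n
  expect_gt(mean(late$stem_count), 100)
})

test_that("evergreens are excluded by a shallow active layer", {
  ls <- small_landscape()
  ls$active_layer[] <- 50
  clim <- stationary_climate(40)
  cfg <- run_config(fire_mode = "off", seed = 15, snapshot_every = 0,
                    forest = forest_params(al_tau_yr = 1e9))  # freeze thaw state
  sim <- fl_run(fl_simulation(ls, clim, config = cfg))
  traits <- species_defaults()
  young <- sim$trees$age[sim$trees$alive] < 40
  sp <- sim$trees$species[sim$trees$alive][young]
  expect_true(all(traits$deciduous[sp]))
})

test_that("the experiment suite enumerates 2 + 6 + 15 runs exactly once", {
  sc <- scenario_configs()
  expect_length(sc, 23L)
  fixed <- Filter(function(cfg) cfg$fire_mode == "fixed", sc)
  expect_length(fixed, 15L)
  combos <- unique(vapply(fixed, function(cfg)
    sprintf("%d|%g", cfg$fixed_fri, cfg$fixed_fi), character(1)))
  expect_length(combos, 15L)
  # sensitivity runs differ from the reference in exactly one factor
  ref <- sc$fire
  for (nm in grep("^sens_", names(sc), value = TRUE)) {
    cfg <- sc[[nm]]
    diffs <- vapply(c("perturb_t", "perturb_p", "perturb_mortality"),
                    function(f) !identical(cfg[[f]], ref[[f]]), TRUE)
    expect_equal(sum(diffs), 1L)
    expect_identical(cfg$fire_mode, "climate_driven")
  }
})

test_that("suite manifests land in per-run directories", {
  ls <- small_landscape()
  clim <- stationary_climate(5)
  dir <- withr::local_tempdir()
  run_experiment_suite(ls, clim, dir, execute = FALSE)
  expect_length(list.files(dir), 23L)
  man <- yaml::read_yaml(file.path(dir, "fixed_fri50_fi1", "manifest.yaml"))
  expect_equal(man$fixed_fri, 50)
  expect_equal(man$fixed_fi, 1)
  expect_error(run_experiment_suite(ls, clim, dir, execute = FALSE),
               "exists")
})

test_that("fire-interval statistics use population spread and handle few fires", {
  s <- compute_fri_stats(c(0, 10, 30))
  expect_equal(s$mean_fri, 15)
  expect_equal(s$sd_fri, 5)           # population sd of {10, 20}
  expect_warning(s1 <- compute_fri_stats(c(7)), "fewer than two")
  expect_true(is.na(s1$mean_fri))
  # geometric-interval oracle at p = 0.03
  set.seed(17)
  years <- which(runif(10000) < 0.03)
  st <- compute_fri_stats(years)
  se <- st$sd_fri / sqrt(st$n_intervals)
  expect_lt(abs(st$mean_fri - 1 / 0.03), 3 * se)
})

test_that("run configs validate their invariants", {
  expect_error(run_config(fire_mode = "fixed"), "fixed_fri")
  expect_error(run_config(perturb_t = 1.1), "0.95")
  cfg <- run_config(fire_mode = "fixed", fixed_fri = 100, fixed_fi = 0.5)
  expect_s3_class(cfg, "fl_config")
})
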