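traits <- species_defaults()

test_that("growth hits the trait rate at the optimum and vanishes under crowding", {
  tr <- make_stand(1, heights = 100)
  opt <- traits$temp_optimum_c[1]
  g <- annual_growth(tr, opt, comp = 0, traits)
  expect_equal(g$height, 100 + traits$growth_rate_cm_yr[1])
  crowded <- annual_growth(tr, opt, comp = 1e9, traits)
  expect_lt(crowded$height - 100, 1e-6)
  cooler <- annual_growth(tr, opt - 5, comp = 0, traits)
  expect_lt(cooler$height, g$height)
  expect_true(all(g$crown_base < g$height))
})

test_that("competition is zero when isolated and additive in neighbors", {
  one <- make_stand(1, heights = 500)
  expect_equal(competition_index(one), 0)
  set.seed(4)
  stand <- make_stand(40, width = 15)
  base <- competition_index(stand)
  extra <- rbind(stand, make_stand(1, width = 15, heights = 1400, seed = 5))
  with_extra <- competition_index(extra)[seq_len(nrow(stand))]
  expect_true(all(with_extra >= base))
  # thinning a crowded stand releases the survivors
  focal <- which.max(base)
  keep <- unique(c(focal, sample(seq_len(nrow(stand)), 20)))
  thinned <- competition_index(stand[keep, ])[1]
  expect_lt(thinned, base[focal] + 1e-12)
})

test_that("competition queries are exact within the radius", {
  # two trees at a known distance: in range iff distance <= radius
  p <- forest_params(comp_radius_m = 10, comp_scale = 1)
  mk <- function(d) {
    df <- make_stand(2, heights = c(100, 800))
    df$x <- c(0, d); df$y <- c(0, 0)
    df
  }
  near <- competition_index(mk(9.99), p)
  far <- competition_index(mk(10.01), p)
  expect_gt(near[1], 0)               # shorter tree sees the taller one
  expect_equal(near[2], 0)            # taller tree ignores shorter ones
  expect_equal(far[1], 0)
  expect_equal(near[1], 8 * (1 - 9.99 / 10), tolerance = 1e-9)
})

test_that("only mature trees seed, and dispersal follows the Gaussian kernel", {
  ls <- small_landscape(water_fraction = 0)
  gs <- matrix(0, ls$nf, nrow(traits))
  young <- make_stand(5, heights = 150)       # below maturity (200 cm)
  set.seed(8)
  out <- produce_and_disperse(young, gs, ls, traits)
  expect_equal(sum(out$ground_seeds), 0)

  # single mature parent in the center; mean deposit distance matches the
  # Rayleigh expectation sd * sqrt(pi / 2)
  tr2 <- traits
  tr2$dispersal_sd_m <- rep(3, 6)
  tr2$seeds_per_year <- rep(6000, 6)
  tr2$release_frac <- rep(1, 6)
  parent <- make_stand(1, heights = 800)
  parent$x <- 18.1; parent$y <- 18.1   # cell interior, off the 0.2 m lattice
  set.seed(9)
  out2 <- produce_and_disperse(parent, gs, ls, tr2)
  cells <- which(out2$ground_seeds[, 1] > 0)
  wts <- out2$ground_seeds[cells, 1]
  ctr <- firelarch:::fine_center(ls, cells)
  d <- sqrt((ctr$x - 18)^2 + (ctr$y - 18)^2)
  n <- sum(wts)
  mean_d <- sum(d * wts) / n
  se <- 3 * sqrt((4 - pi) / 2) / sqrt(n)
  expect_lt(abs(mean_d - 3 * sqrt(pi / 2)), 3 * se + ls$fine_res)

  # with a vanishing kernel all seeds stay in the parent's cell
  tr2$dispersal_sd_m <- rep(1e-9, 6)
  set.seed(10)
  out3 <- produce_and_disperse(parent, gs, ls, tr2)
  expect_equal(which(out3$ground_seeds[, 1] > 0),
               firelarch:::fine_index(ls, 18.1, 18.1))
})

test_that("establishment is gated by the species active-layer threshold", {
  ls <- small_landscape()
  ls$active_layer[] <- 150
  gs <- matrix(0, ls$nf, nrow(traits))
  cell <- firelarch:::fine_index(ls, 10, 10)
  gs[cell, 4] <- 1000    # Siberian spruce needs 200 cm of thaw
  gs[cell, 1] <- 1000    # Dahurian larch needs 20 cm
  set.seed(11)
  est <- establish(gs, ls, traits, gs_t = 12)
  expect_false(any(est$seedlings$species == 4))
  expect_true(any(est$seedlings$species == 1))

  ls$active_layer[] <- 25                       # larch fine, all evergreens out
  gs2 <- matrix(0, ls$nf, nrow(traits))
  gs2[cell, ] <- 1000
  set.seed(12)
  est2 <- establish(gs2, ls, traits, gs_t = 12)
  expect_true(all(est2$seedlings$species %in% which(traits$deciduous)))
})

test_that("litter suppresses germination", {
  ls <- small_landscape()
  gs <- matrix(0, ls$nf, nrow(traits))
  cells <- which(!ls$water_fine)[1:4000]
  gs[cells, 1] <- 40
  ls$litter[] <- 0
  set.seed(13)
  bare <- nrow(establish(gs, ls, traits, gs_t = 12)$seedlings)
  ls$litter[] <- 13
  set.seed(13)
  buried <- nrow(establish(gs, ls, traits, gs_t = 12)$seedlings)
  expect_gt(bare, 3 * buried)
})

test_that("mortality follows the background-age-competition decomposition", {
  expect_equal(mortality_prob(500, 0, 1L, traits), 1)   # beyond max age
  expect_equal(mortality_prob(10, 0, 1L, traits),
               traits$background_mortality[1], tolerance = 1e-4)
  # cohort survival is geometric in the background rate
  set.seed(14)
  n <- 10000
  a <- 10
  alive <- rep(TRUE, n)
  for (k in seq_len(a)) alive[alive] <-
      runif(sum(alive)) >= mortality_prob(k, 0, 1L, traits)
  expect_lt(abs(mean(alive) - (1 - traits$background_mortality[1])^a),
            3 * sqrt(0.85 * 0.15 / n))
  # competition raises the hazard monotonically
  p <- mortality_prob(10, c(0, 0.5, 2, 10), 1L, traits)
  expect_true(all(diff(p) > 0))
})

test_that("litter regrows at exactly 0.5 cm per year with disturbances off", {
  ls <- small_landscape()
  litter <- rep(0, ls$nf)
  for (k in 1:10) litter <- update_litter(litter, ls$water_fine,
                                          disturb = FALSE)
  expect_equal(unique(litter[!ls$water_fine]), 5.0)
  for (k in 1:100) litter <- update_litter(litter, ls$water_fine,
                                           disturb = FALSE)
  p <- forest_params()
  expect_equal(unique(litter[!ls$water_fine]), p$litter_cap_cm)  # capped
})

test_that("stochastic litter stays bounded and clears from water", {
  ls <- small_landscape(water_fraction = 0.25)
  set.seed(15)
  litter <- ls$litter
  p <- forest_params()
  for (k in 1:50) litter <- update_litter(litter, ls$water_fine, p)
  expect_true(all(litter >= 0))
  expect_true(all(litter <= p$litter_cap_cm))
  expect_true(all(litter[ls$water_fine] == 0))
})

test_that("active layer deepens when litter insulation is removed", {
  ls <- small_landscape()
  p <- forest_params()
  ti <- 1740                      # stationary study-region thaw index
  bare <- covered <- rep(60, ls$nf)
  for (k in 1:40) {
    bare <- update_active_layer(bare, ti, rep(0, ls$nf), ls$water_fine, p)
    covered <- update_active_layer(covered, ti, rep(13, ls$nf),
                                   ls$water_fine, p)
  }
  land <- !ls$water_fine
  expect_true(all(bare[land] > covered[land]))
  # converged to the fixed point, no oscillation
  eq <- p$stefan_coef * sqrt(ti) * exp(-p$k_ins * 13)
  expect_lt(max(abs(covered[land] - eq)), 1e-3)
})

test_that("thaw equilibria match the cold-stage and warm-stage calibration", {
  p <- forest_params()
  cold <- p$stefan_coef * sqrt(1000) * exp(-p$k_ins * 13)
  warm <- p$stefan_coef * sqrt(2000) * exp(-p$k_ins * 0)
  expect_equal(cold, 60, tolerance = 0.05)
  expect_equal(warm, 100, tolerance = 0.05)
})
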