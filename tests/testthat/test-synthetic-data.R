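test_that("geometry tiles the domain with consistent membership and layers", {
  g1 <- gen_geometry(n_polygons = 1, depth_cuts = c(10, 50), seed = 3)
  expect_true(all(g1$cells$polygon == 1))
  expect_equal(sum(g1$cells$weight), 1)

  g <- tiny_geometry()
  # every cell belongs to exactly one polygon; weights per polygon sum to 1
  expect_equal(nrow(g$cells), g$nx * g$ny)
  w <- tapply(g$cells$weight, g$cells$polygon, sum)
  expect_equal(unname(as.vector(w)), rep(1, g$n_polygons))
  # default cuts give up to 6 water layers
  gd <- gen_geometry(n_polygons = 8, seed = 4, basin_depth = 3500)
  expect_equal(max(gd$polygons$n_water_layers), 6)
  expect_identical(length(gd$depth_cuts) + 1L, 6L)
  # determinism
  expect_identical(gen_geometry(seed = 9)$cells, gen_geometry(seed = 9)$cells)
  # invalid cuts rejected
  expect_error(gen_geometry(depth_cuts = c(50, 10)), "increasing")
})

test_that("oil field conserves mass, partitions layers and closes its budget", {
  g <- tiny_geometry()
  gf <- gen_geometry(n_polygons = 4, depth_cuts = c(10, 50, 200),
                     grid_resolution = 0.25, seed = 11)
  # no decay, no drift, compact blob kept in the interior: mass constant
  f0 <- gen_oil_field(gf, release_site = c(mean(g$lon_range), mean(g$lat_range)),
                      release_days = 5, track_days = 12, amount = 100,
                      decay_rate = 0, drift_surface = c(0, 0),
                      drift_deep = c(0, 0), sigma0 = 0.4,
                      diffusivity = 1e-5, seed = 2)
  m <- oil_total_mass(f0)
  expect_lt(max(abs(diff(m[5:12]))) / m[5], 1e-6)   # constant to 1e-6 per day
  # all mass to the deep layer leaves the surface identically zero
  fd <- gen_oil_field(g, surface_deep_fractions = c(0, 1), release_days = 4,
                      track_days = 8, seed = 2)
  expect_equal(sum(fd$conc[, 1, ]), 0)
  expect_gt(sum(fd$conc[, fd$deep_layer, ]), 0)
  # zero new release after release_days, positive decay: mass strictly falls,
  # matching the closed-form exponential decay of total mass
  lam <- 0.08
  f1 <- gen_oil_field(g, release_site = c(mean(g$lon_range), mean(g$lat_range)),
                      release_days = 4, track_days = 20, amount = 100,
                      decay_rate = lam, drift_surface = c(0, 0),
                      drift_deep = c(0, 0), sigma0 = 0.4,
                      diffusivity = 1e-5, seed = 2)
  m1 <- oil_total_mass(f1)
  expect_true(all(diff(m1[4:20]) < 0))
  # closed-form exponential-decay oracle on the normalised mass series
  oracle <- vapply(5:20, function(d) sum(exp(-lam * (d - 1:4))), 0)
  oracle <- oracle / sum(exp(-lam * (4 - 1:4)))
  expect_lt(max(abs(m1[5:20] / m1[4] - oracle) / oracle), 1e-5)
  # per-day budget closes exactly: injected - decayed - advected = dM
  f2 <- gen_oil_field(g, release_days = 10, track_days = 30, seed = 6)
  b <- f2$budget
  dM <- diff(c(0, oil_total_mass(f2)))
  expect_lt(max(abs(dM - (b$injected - b$decayed - b$advected_out))) /
              max(oil_total_mass(f2)), 1e-9)
  expect_error(gen_oil_field(g, decay_rate = -1), "non-negative")
  expect_error(gen_oil_field(g, release_days = 20, track_days = 10), "track_days")
})

test_that("food web has the guild structure, consistent trophic levels and diets", {
  w <- tiny_web()
  fish_guilds <- c("snappers", "groupers", "sciaenids", "elasmobranchs",
                   "large pelagic fish", "small pelagic fish",
                   "small demersal and reef fish", "large demersal fish")
  expect_true(all(fish_guilds %in% w$groups$guild))
  expect_true(all(rowSums(w$diet) <= 1 + 1e-9))
  # recursive trophic-level definition holds to 1e-9
  P <- w$diet / pmax(rowSums(w$diet), 1e-12)
  basal <- w$groups$type %in% c("producer", "detritus") | rowSums(w$diet) == 0
  tl <- w$groups$trophic_level
  resid <- tl - (1 + as.vector(P %*% tl))
  expect_lt(max(abs(resid[!basal])), 1e-9)
  expect_equal(tl[w$groups$code == "PHY"], 1)
  # a pure herbivore sits at TL 2
  d2 <- matrix(0, 2, 2, dimnames = list(c("A", "PHY"), c("A", "PHY")))
  d2["A", "PHY"] <- 1
  expect_equal(unname(trophic_levels(d2, c("pool", "producer"))[1]), 2)
  # a group eating only benthic prey has benthic fraction 1
  expect_equal(benthic_diet_fraction(c(0.4, 0.2, 0), c(TRUE, TRUE, FALSE)), 1)
  bad <- default_diet <- w$diet
  bad[1, ] <- 0.5
  expect_error(gen_food_web(diet = bad), "<= 1")
})

test_that("closure schedule stays in its window with a monotone growth phase", {
  g <- tiny_geometry()
  cl <- gen_closures(g, start_day = 100, duration_days = 365,
                     peak_fraction = 0.7, seed = 1)
  expect_true(all(cl$closed >= 0 & cl$closed <= 1))
  expect_equal(dim(cl$closed)[1], 365)
  # zero outside the window
  expect_equal(sum(closed_fraction(cl, 99, g$n_polygons)), 0)
  expect_equal(sum(closed_fraction(cl, 100 + 365, g$n_polygons)), 0)
  expect_gt(sum(closed_fraction(cl, 200, g$n_polygons)), 0)
  # growth phase: closed area non-decreasing day over day
  area <- apply(cl$closed[, , 1], 1, sum)
  grow <- ceiling(365 / 3)
  expect_true(all(diff(area[1:grow]) >= -1e-12))
  # degenerate and invalid cases
  expect_equal(sum(gen_closures(g, peak_fraction = 0)$closed), 0)
  expect_error(gen_closures(g, peak_fraction = 1.4), "peak_fraction")
})

test_that("larval losses match the target moments and bounds", {
  w <- tiny_web()
  # sd = 0 is exact; mean 1 is the total-kill bounding case
  expect_equal(gen_larval_loss(w, sd = 0)$loss_fraction[w$groups$is_fish],
               rep(0.058, 8))
  expect_equal(gen_larval_loss(w, mean = 1, sd = 0)$loss_fraction[
    w$groups$is_fish], rep(1, 8))
  expect_equal(gen_larval_loss(w, sd = 0)$loss_fraction[!w$groups$is_fish],
               rep(0, 4))
  # Monte-Carlo check of the generator moments: 1e4 draws
  big <- data.frame(code = sprintf("G%05d", 1:10000), is_fish = TRUE)
  draws <- gen_larval_loss(big, mean = 0.058, sd = 0.045, seed = 42)$loss_fraction
  expect_true(all(draws >= 0 & draws <= 1))
  expect_lt(abs(mean(draws) - 0.058), 3 * 0.045 / sqrt(1e4))
  expect_lt(abs(sd(draws) - 0.045), 0.005)
  # determinism
  expect_identical(gen_larval_loss(w, seed = 3)$loss_fraction,
                   gen_larval_loss(w, seed = 3)$loss_fraction)
  expect_error(gen_larval_loss(w, mean = -1), "non-negative")
})
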