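p0 <- dose_response_params()

test_that("hockey-stick mortality is zero below threshold, log-linear above", {
  expect_equal(mortality_effect(p0$beta / 2 / p0$K, p0), 0)
  expect_equal(mortality_effect(p0$beta / p0$K, p0), 0)
  # at K*phi = beta*e the effect is alpha/omega
  expect_equal(mortality_effect(p0$beta * exp(1) / p0$K, p0),
               0.2885 / 15, tolerance = 1e-12)
  # continuity at the knot
  eps <- 1e-9
  expect_lt(mortality_effect((p0$beta + eps) / p0$K, p0), 1e-10)
  # strictly increasing and concave above the knot
  phi <- seq(p0$beta / p0$K * 1.01, p0$beta / p0$K * 20, length.out = 50)
  m <- mortality_effect(phi, p0)
  expect_true(all(diff(m) > 0))
  expect_true(all(diff(diff(m)) < 0))
  expect_error(mortality_effect(-1, p0), "non-negative")
})

test_that("growth effect and multiplier behave at the knot and the clamp", {
  g0 <- growth_effect(0, p0)
  expect_equal(g0$effect, 0)
  expect_equal(g0$multiplier, 1)
  expect_equal(growth_effect(p0$delta * exp(1) / p0$K, p0)$effect,
               0.0531 / 15, tolerance = 1e-12)
  ghuge <- growth_effect(1e150, p0)
  expect_equal(ghuge$multiplier, 0)
  expect_gte(ghuge$multiplier, 0)
})

test_that("mortality effect is monotone in K and in beta", {
  phi <- 2
  Ks <- c(400, 600, 800, 1000)
  m_K <- vapply(Ks, function(K) mortality_effect(phi, p0, K = K), 0)
  expect_true(all(diff(m_K) >= 0))
  # effect is non-increasing in beta: raising the threshold weakens it
  betas <- c(362.9722, 544.4584, 725.9445, 907.4306)
  m_b <- vapply(betas, function(b) {
    p <- dose_response_params(beta = b)
    mortality_effect(phi, p)
  }, 0)
  expect_true(all(diff(m_b) <= 0))
})

test_that("body burden clears, decays exactly and converges to the closed form", {
  # 99% clearance in 20 days at rho = 0.2424
  phi <- 1
  for (d in 1:20) phi <- update_body_burden(phi, 0, mu = 1, rho = p0$rho)
  expect_lt(phi, 0.01)
  # pure decay is exact
  expect_equal(phi, exp(-p0$rho * 20), tolerance = 1e-12)
  # constant forcing converges to mu*c/(1 - exp(-rho)); oracle: iterate the
  # recursion to its fixed point and compare the geometric-series closed form
  cc <- 3.7
  phi <- 0
  for (d in 1:400) phi <- update_body_burden(phi, cc, mu = 1, rho = p0$rho)
  expect_equal(phi, cc / (1 - exp(-p0$rho)), tolerance = 1e-10)
  # boundedness under arbitrary bounded forcing
  set.seed(31)
  O <- runif(500, 0, 5)
  phi <- 0
  for (d in seq_along(O)) {
    phi <- update_body_burden(phi, O[d], mu = 0.1, rho = p0$rho)
    expect_gte(phi, 0)
  }
  expect_lte(phi, 0.1 * 5 / (1 - exp(-p0$rho)) + 1e-12)
  expect_error(update_body_burden(-1, 0, 1, 0.1), "non-negative")
})

test_that("modifier combination is a convex combination", {
  expect_equal(combine_modifiers(0.02, 0.04, 0), 0.02)
  expect_equal(combine_modifiers(0.02, 0.04, 1), 0.04)
  expect_equal(combine_modifiers(0.02, 0.04, 0.5), 0.03)
  set.seed(8)
  for (k in 1:50) {
    a <- runif(1); b <- runif(1); f <- runif(1)
    out <- combine_modifiers(a, b, f)
    expect_gte(out, min(a, b) - 1e-12)
    expect_lte(out, max(a, b) + 1e-12)
  }
  expect_equal(benthic_diet_fraction(c(0, 0, 0), c(TRUE, FALSE, TRUE)), 0)
  expect_equal(benthic_diet_fraction(c(0.3, 0.7), c(TRUE, FALSE)), 0.3)
})

test_that("polygon aggregation matches a brute-force per-cell oracle", {
  g <- tiny_geometry()
  f <- gen_oil_field(g, release_days = 3, track_days = 6, seed = 13)
  # uniform field: every polygon-layer mean is c, oiled fraction 1
  fu <- f
  fu$conc[] <- 2.5
  osu <- aggregate_to_polygons(fu, g)
  expect_equal(range(osu$water_conc), c(2.5, 2.5))
  expect_equal(range(osu$oiled_cell_fraction), c(1, 1))
  # random field against independent per-cell averaging
  os <- aggregate_to_polygons(f, g)
  for (p in seq_len(g$n_polygons)) {
    cells <- g$cells$cell[g$cells$polygon == p]
    for (l in c(1, f$deep_layer)) {
      expect_equal(os$water_conc[4, p, l], mean(f$conc[4, l, cells]),
                   tolerance = 1e-12)
    }
    anyoil <- apply(f$conc[3, , cells, drop = FALSE], 3, max) > 1e-3
    expect_equal(os$oiled_cell_fraction[3, p], mean(anyoil), tolerance = 1e-12)
  }
  # half the cells at 2c, half at zero: mean c, oiled fraction one half
  p1 <- 1
  cells <- g$cells$cell[g$cells$polygon == p1]
  half <- cells[seq_len(floor(length(cells) / 2))]
  fh <- f
  fh$conc[] <- 0
  fh$conc[1, 1, half] <- 2
  osh <- aggregate_to_polygons(fh, g)
  expect_equal(osh$water_conc[1, p1, 1], 2 * length(half) / length(cells))
  expect_equal(osh$oiled_cell_fraction[1, p1], length(half) / length(cells))
})

test_that("full modifier pipeline weights unoiled cells and depurates", {
  g <- tiny_geometry()
  w <- tiny_web()
  f <- gen_oil_field(g, release_days = 30, track_days = 60, seed = 21)
  os <- aggregate_to_polygons(f, g)
  # zero oil everywhere: no mortality, growth untouched
  os0 <- os
  os0$water_conc[] <- 0; os0$bottom_conc[] <- 0; os0$oiled_cell_fraction[] <- 0
  tox0 <- polygon_modifier_series(os0, g, w, p0, n_days = 80)
  expect_equal(max(tox0$m_oil), 0)
  expect_equal(min(tox0$g_mult), 1)
  # halving the oiled-cell fraction at the same within-patch concentration
  # halves the polygon-scale effect
  mk <- function(frac) {
    os2 <- os0
    os2$oiled_cell_fraction[] <- frac
    os2$water_conc[] <- 4 * frac     # within-patch concentration 4 ppb
    os2$bottom_conc[] <- 4 * frac
    polygon_modifier_series(os2, g, w, p0, n_days = 80)
  }
  t1 <- mk(1); t5 <- mk(0.5)
  expect_equal(max(t5$m_oil), max(t1$m_oil) / 2, tolerance = 1e-9)
  # after forcing ends the modifier decays monotonically to zero with the
  # depuration envelope
  tox <- polygon_modifier_series(os, g, w, p0, n_days = 200, start_day = 1)
  worst <- which.max(apply(tox$m_oil, 2, max))
  gworst <- which.max(apply(tox$m_oil, 3, max))
  series <- tox$m_oil[, worst, gworst]
  tail <- series[61:200]
  expect_true(all(diff(tail[tail > 0]) <= 1e-12))
  expect_lt(series[150], 1e-10)
  # burden envelope after forcing is bounded by exp(-rho t)
  phi_end <- tox$phi_benthic[60, worst]
  expect_lte(tox$phi_benthic[90, worst], phi_end * exp(-p0$rho * 29) + 1e-9)
  # missing days rejected
  os_bad <- os
  os_bad$days <- c(1:10, 12:60)
  expect_error(polygon_modifier_series(os_bad, g, w, p0), "contiguous")
})
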