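# Minimal run_output-shaped objects for constructed-input tests.
fake_run <- function(B, groups, cells = NULL, numbers = NULL,
                     rN = NULL, sN = NULL, consumption = NULL,
                     pred_numbers = NULL, catch = NULL, label = "fake") {
  n_months <- dim(B)[1]
  structure(list(label = label, months = seq_len(n_months), biomass = B,
                 numbers = numbers, rN = rN, sN = sN,
                 consumption = consumption, pred_numbers = pred_numbers,
                 catch = catch, cells = cells, groups = groups,
                 spill_day = 110),
            class = "run_output")
}

fake_groups <- function(n = 4, tl = NULL) {
  data.frame(code = paste0("G", seq_len(n)), guild = paste0("G", seq_len(n)),
             is_fish = TRUE, habitat = rep(c("pelagic", "demersal"),
                                           length.out = n),
             type = "fish", maturity_class = 2L,
             trophic_level = if (is.null(tl)) seq(2, length.out = n) else tl)
}

test_that("relative biomass matches a brute-force recomputation", {
  set.seed(12)
  g <- fake_groups(4)
  B1 <- array(runif(24 * 4 * 3, 1, 2), c(24, 4, 3))
  B0 <- array(runif(24 * 4 * 3, 1, 2), c(24, 4, 3))
  ra <- fake_run(B1, g); rb <- fake_run(B0, g)
  # identical runs give a flat ratio of one
  same <- relative_biomass(ra, ra, polygon_subset = 1:3)
  expect_equal(range(same$ratio), c(1, 1))
  # explicit subset equals independent per-month summation
  cmp <- relative_biomass(ra, rb, polygon_subset = c(1, 3), guilds = FALSE)
  for (m in c(1, 10, 24)) for (j in 1:4) {
    expect_equal(unname(cmp$ratio[m, paste0("G", j)]),
                 sum(B1[m, j, c(1, 3)]) / sum(B0[m, j, c(1, 3)]),
                 tolerance = 1e-12)
  }
  # top-k rule with all polygons equals the whole-domain ratio
  all_sub <- relative_biomass(ra, rb, top_frac = 1, guilds = FALSE)
  whole <- relative_biomass(ra, rb, polygon_subset = 1:3, guilds = FALSE)
  expect_equal(all_sub$ratio, whole$ratio)
  expect_error(relative_biomass(ra, fake_run(B0[1:10, , , drop = FALSE], g)),
               "calendar")
})

test_that("biomass minima report the right month with documented tie-breaks", {
  g <- fake_groups(1)
  v <- matrix(1, 36, 1, dimnames = list(NULL, "G1"))
  mk <- function(x) list(ratio = x, months = seq_len(nrow(x)))
  # flat series: minimum one, undefined month
  out <- biomass_minimum(mk(v))
  expect_equal(out$min_ratio, 1)
  expect_true(is.na(out$month_of_min))
  # V-shape with the knot at absolute month 14 (about 10 months post-spill)
  v2 <- v; v2[, 1] <- 1 - pmax(0, 10 - abs(seq_len(36) - 14)) / 20
  out2 <- biomass_minimum(mk(v2), spill_day = 110)
  expect_equal(out2$month_of_min, 14 - 110 / (365 / 12), tolerance = 1e-9)
  # ties take the earliest month
  v3 <- v; v3[10, 1] <- 0.5; v3[20, 1] <- 0.5
  expect_equal(biomass_minimum(mk(v3), spill_day = 0)$month_of_min, 10)
})

test_that("recovery time applies the sustained-threshold criterion", {
  mk <- function(x) list(ratio = matrix(x, ncol = 1,
                                        dimnames = list(NULL, "G")),
                         months = seq_along(x))
  horizon <- 50 * 12
  # never dips below the threshold: recovery zero
  expect_equal(recovery_time(mk(rep(1, horizon)), spill_day = 0)$recovery_years, 0)
  # permanently depressed: did not recover
  out <- recovery_time(mk(rep(0.9, horizon)), spill_day = 0)
  expect_true(out$dnr)
  expect_true(is.na(out$recovery_years))
  # step recovery at year 7, sustained: recovers in 7 years
  x <- c(rep(0.5, 84), rep(0.995, horizon - 84))
  expect_equal(recovery_time(mk(x), spill_day = 0)$recovery_years, 7)
  # a brief excursion above the threshold does not count
  y <- c(rep(0.5, 84), rep(0.995, 6), rep(0.5, 24), rep(0.995, horizon - 114))
  expect_equal(recovery_time(mk(y), spill_day = 0)$recovery_years, 114 / 12)
  # recovery time is non-decreasing in the threshold; DNR iff never sustained
  set.seed(4)
  z <- pmin(1.05, 0.4 + cumsum(runif(240, 0, 0.01)))
  rts <- vapply(c(0.8, 0.9, 0.99), function(th) {
    r <- recovery_time(mk(z), threshold = th, spill_day = 0)
    if (r$dnr) Inf else r$recovery_years
  }, 0)
  expect_true(all(diff(rts) >= 0))
})

test_that("age structure metrics recover composition and maturity ratios", {
  g <- fake_groups(1)
  g$maturity_class <- 4L
  cells <- data.frame(gi = 1, age = 1:6)
  N <- array(0, c(3, 6, 2))
  N[, 2, ] <- 5          # everything in age class 2
  run <- fake_run(array(1, c(3, 1, 2)), g, cells = cells, numbers = N)
  am <- age_structure_metrics(run)
  expect_equal(am$age_proportions[1, ], c(0, 1, 0, 0, 0, 0))
  # uniform numbers with maturity at the mid age: ratio about one
  N2 <- array(1, c(3, 6, 2))
  run2 <- fake_run(array(1, c(3, 1, 2)), g, cells = cells, numbers = N2)
  am2 <- age_structure_metrics(run2)
  expect_equal(unname(am2$mature_ratio[1, 1]), 1)
})

test_that("condition factor is the reserve to structural ratio", {
  g <- fake_groups(1)
  cells <- data.frame(gi = 1, age = 1:3)
  sN <- matrix(2, 5, 3)
  rN <- matrix(4, 5, 3)
  N <- array(1, c(5, 3, 2))
  run <- fake_run(array(1, c(5, 1, 2)), g, cells = cells, numbers = N,
                  rN = rN, sN = sN)
  expect_equal(unname(condition_factor(run)[, 1]), rep(2, 5))
})

test_that("consumption matrix is per capita and doubles when predators halve", {
  g <- fake_groups(2)
  g$guild <- c("A", "B")
  cons <- array(0, c(12, 2, 2))
  cons[, 1, 2] <- 31        # guild A eats guild B
  predN <- matrix(c(10, 5), 12, 2, byrow = TRUE)
  run <- fake_run(array(1, c(12, 2, 2)), g, consumption = cons,
                  pred_numbers = predN)
  cm <- consumption_matrix(run, months = 1:12)
  expect_equal(unname(cm$per_capita["A", "B"]), 12 * 31 / 10 / 365)
  # halve predator numbers, same intake: per-capita doubles
  run2 <- run; run2$pred_numbers <- predN / 2
  cm2 <- consumption_matrix(run2, months = 1:12)
  expect_equal(unname(cm2$per_capita["A", "B"]),
               2 * unname(cm$per_capita["A", "B"]))
  # no predation, zero matrix
  run0 <- run; run0$consumption[] <- 0
  expect_equal(sum(consumption_matrix(run0)$per_capita), 0)
})

test_that("ecosystem indicators match their closed forms", {
  g <- fake_groups(4, tl = c(2, 2, 2, 2))
  B <- array(1, c(2, 4, 1))       # four equal-biomass groups
  run <- fake_run(B, g)
  ind <- ecosystem_indicators(run)
  expect_equal(ind$shannon[1], log(4), tolerance = 1e-12)
  expect_equal(ind$mean_tl[1], 2)
  # a single group has zero diversity
  B1 <- B; B1[, 2:4, ] <- 0
  expect_equal(ecosystem_indicators(fake_run(B1, g))$shannon[1], 0)
  # shares (0.75, 0.25): direct evaluation of -sum p log p
  B2 <- array(0, c(1, 4, 1)); B2[1, 1, ] <- 3; B2[1, 2, ] <- 1
  expect_equal(ecosystem_indicators(fake_run(B2, g))$shannon[1],
               -(0.75 * log(0.75) + 0.25 * log(0.25)), tolerance = 1e-12)
  expect_equal(round(ecosystem_indicators(fake_run(B2, g))$shannon[1], 4),
               0.5623)
  # brute-force recomputation of the mean trophic level
  set.seed(9)
  g3 <- fake_groups(4, tl = c(1, 2.2, 3.1, 4.4))
  B3 <- array(runif(4 * 4 * 2, 0.1, 3), c(4, 4, 2))
  ind3 <- ecosystem_indicators(fake_run(B3, g3))
  for (m in 1:4) {
    b <- rowSums(matrix(B3[m, , ], 4, 2))
    expect_equal(ind3$mean_tl[m], sum(b * g3$trophic_level) / sum(b),
                 tolerance = 1e-9)
  }
})

test_that("catch ratios handle zero baselines with a sentinel", {
  g <- fake_groups(2)
  mk <- function(x) fake_run(array(1, c(12, 2, 1)), g,
                             catch = matrix(x, 3, 2,
                                            dimnames = list(NULL, c("a", "b"))))
  same <- catch_delta(mk(5), mk(5))
  expect_equal(range(same), c(1, 1))
  num <- mk(c(2, 4, 0, 1, 1, 1))
  den <- mk(c(4, 4, 0, 1, 0, 2))
  out <- catch_delta(num, den)
  expect_equal(unname(out[1, "a"]), 0.5)
  expect_true(is.na(out[3, "a"]))
  expect_true(is.na(out[2, "b"]))
})
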