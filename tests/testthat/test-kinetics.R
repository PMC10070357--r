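test_that("kinetic schemes derive populations and exchange times", {
  sc <- kinetic_scheme(data.frame(label = c("A", "B"), E = c(0.3, 0.8)),
                       rates = matrix(c(0, 300, 700, 0), 2, 2, byrow = TRUE))
  expect_equal(sc$populations, c(0.7, 0.3))
  expect_equal(sc$tau_ex, 1 / 1000)
  ## distance <-> efficiency round trip
  expect_equal(fret_efficiency_from_distance(49, 49), 0.5)
  expect_equal(distance_from_fret_efficiency(
    fret_efficiency_from_distance(60, 49), 49), 60)
})

test_that("state trajectories have stationary occupancy and exponential dwells", {
  sc <- kinetic_scheme(data.frame(label = c("A", "B"), E = c(0, 1)),
                       rates = matrix(c(0, 1282, 1282, 0), 2, 2, byrow = TRUE))
  set.seed(10)
  path <- simulate_state_trajectory(sc, 100)
  tt <- c(path$t, 100)
  dwell <- diff(tt)
  occ1 <- sum(dwell[path$state == 1]) / 100
  expect_equal(occ1, 0.5, tolerance = 0.02)
  expect_lt(abs(mean(dwell) - 1 / 1282), 8e-6)

  sc2 <- kinetic_scheme(data.frame(label = c("A", "B"), E = c(0, 1)),
                        rates = matrix(c(0, 300, 700, 0), 2, 2, byrow = TRUE))
  set.seed(11)
  p2 <- simulate_state_trajectory(sc2, 200)
  t2 <- c(p2$t, 200)
  occ <- sum(diff(t2)[p2$state == 1]) / 200
  expect_equal(occ, 0.7, tolerance = 0.02)

  ## single state: constant path
  one <- kinetic_scheme(data.frame(label = "S", E = 0.5))
  pa <- simulate_state_trajectory(one, 1)
  expect_equal(pa$state, 1L)
})

test_that("occupancy-time distribution is normalized and matches Monte Carlo", {
  k <- 1282
  T <- 1e-3
  occ <- occupancy_time_distribution(k, k, T, n_nodes = 61)
  expect_lt(abs(sum(occ$atoms$w) + sum(occ$nodes$w) - 1), 1e-6)
  mean_t1 <- sum(occ$atoms$w * occ$atoms$t1) + sum(occ$nodes$w * occ$nodes$t1)
  expect_equal(mean_t1, T / 2, tolerance = 1e-8)

  ## Monte-Carlo oracle: CTMC paths, sup-norm of the CDF on a grid
  sc <- kinetic_scheme(data.frame(label = c("A", "B"), E = c(0, 1)),
                       rates = matrix(c(0, k, k, 0), 2, 2, byrow = TRUE))
  set.seed(12)
  mc <- replicate(20000, {
    p <- simulate_state_trajectory(sc, T)
    sum(diff(c(p$t, T))[p$state == 1])
  })
  ## fine-grid CDF from the analytic density (trapezoid), atoms added
  t1g <- seq(1e-8, T - 1e-8, length.out = 2001)
  occf <- occupancy_time_distribution(k, k, T, n_nodes = 61)
  dens <- local({
    p1 <- 0.5; u <- 2 * sqrt(k * k * t1g * (T - t1g))
    pref <- exp(u - k * t1g - k * (T - t1g))
    pref * ((p1 * k + p1 * k) * besselI(u, 0, TRUE) +
              (p1 * sqrt(k^2 * t1g / (T - t1g)) +
                 p1 * sqrt(k^2 * (T - t1g) / t1g)) * besselI(u, 1, TRUE))
  })
  cdf_an <- function(q) {
    sel <- t1g <= q
    occf$atoms$w[2] * 1 + sum(dens[sel]) * (t1g[2] - t1g[1]) +
      if (q >= T) occf$atoms$w[1] else 0
  }
  qs <- seq(0.05e-3, 0.95e-3, length.out = 19)
  gap <- vapply(qs, function(q) abs(mean(mc <= q) - cdf_an(q)), 0)
  expect_lt(max(gap), 0.015)
})

test_that("frozen and one-way chains give the degenerate distributions", {
  z <- occupancy_time_distribution(0, 0, 1e-3)
  expect_equal(sum(z$atoms$w), 1)
  expect_equal(nrow(z$nodes), 0L)
  ## one-way decay keeps total mass
  ow <- occupancy_time_distribution(1000, 0, 1e-3)
  expect_lt(abs(sum(ow$atoms$w) + sum(ow$nodes$w) - 1), 1e-6)
})

test_that("scenario schemes encode the study conditions", {
  fa <- scenario_scheme("full_agonist")
  expect_equal(fa$truth$hf_population, 0.76)
  expect_equal(fa$truth$tau_ex_s, 390e-6)
  expect_equal(fa$truth$lf_fraction, 0.15)
  pa <- scenario_scheme("partial_agonist")
  expect_equal(pa$truth$hf_population, 0.56)
  ap <- scenario_scheme("apo")
  expect_equal(ap$truth$hf_population, 0.20)
  expect_gt(ap$truth$tau_ex_s, 0.1)
  ## rates consistent with tau_ex and the pair occupancy
  pair <- fa$schemes[[2]]
  expect_equal(1 / (pair$rates[1, 2] + pair$rates[2, 1]), 390e-6)
  expect_equal(pair$populations[2], 0.76 / 0.85, tolerance = 1e-9)
})
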