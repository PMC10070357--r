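test_that("burst binning applies the truncation and filter rules", {
  ## one burst of 3.2 ms at a steady rate: 1 ms bins -> 3 bins
  set.seed(20)
  n <- 320
  t_s <- sort(runif(n, 0, 3.2e-3)) + 0.01
  det <- sample(c("Bpar", "Rpar"), n, TRUE)
  nano <- ifelse(det == "Bpar", 300L, 600L)
  ps <- photon_stream(floor(t_s * 26.67e6), nano, det, windows = gate_windows())
  bt <- data.frame(i_start = 1L, i_end = n, n_photons = n,
                   t_start_s = t_s[1], t_end_s = t_s[n],
                   duration_s = t_s[n] - t_s[1])
  pd <- bin_bursts(ps, bt, identity_corrections(), durations = 1e-3,
                   spr_range = c(0, 1))
  expect_equal(nrow(pd$sets[[1]]$bins), 3L)

  ## a bin with 12 photons is excluded by the minimum-photon rule
  few <- data.frame(i_start = 1L, i_end = 12L, n_photons = 12L,
                    t_start_s = t_s[1], t_end_s = t_s[12],
                    duration_s = 1.1e-3)
  pd2 <- bin_bursts(ps, few, identity_corrections(), durations = 1e-3,
                    spr_range = c(0, 1))
  expect_equal(nrow(pd2$sets[[1]]$bins), 0L)

  ## stoichiometry filter removes acceptor-bleached bins
  pd3 <- bin_bursts(ps, bt, identity_corrections(), durations = 1e-3,
                    spr_range = c(0.2, 0.6))
  expect_true(all(pd3$sets[[1]]$bins$S_PR >= 0.2 & pd3$sets[[1]]$bins$S_PR <= 0.6))
})

test_that("expected histograms are degenerate, linear and normalized", {
  pd <- sample_pda_bins(data.frame(R_mean = 80, R_sigma = 0.01), areas = 1,
                        n_bins = 800, seed = 2)
  tabs <- pda_precompute_tables(pd)
  ## one static state in the no-FRET limit: essentially all mass in the
  ## single zero-efficiency histogram bin
  st0 <- data.frame(R_mean = 500, R_sigma = 0.001)
  m0 <- list(states = st0, areas = 1, R0 = 49)
  h0 <- pda_expected_histogram(pd, m0, tabs)$expected[[1]]
  expect_gt(max(h0) / sum(h0), 1 - 1e-4)

  ## two static states without exchange: mixture linearity
  stA <- data.frame(R_mean = c(60, 40), R_sigma = 2)
  mmix <- list(states = stA, areas = c(0.3, 0.7), R0 = 49)
  h_mix <- pda_expected_histogram(pd, mmix, tabs)$expected[[1]]
  h1 <- pda_expected_histogram(pd, list(states = stA[1, ], areas = 1, R0 = 49),
                               tabs)$expected[[1]]
  h2 <- pda_expected_histogram(pd, list(states = stA[2, ], areas = 1, R0 = 49),
                               tabs)$expected[[1]]
  expect_equal(h_mix, 0.3 * h1 + 0.7 * h2, tolerance = 1e-8)
  expect_equal(sum(h_mix), sum(pd$sets[[1]]$hist), tolerance = 1e-6)
})

test_that("dynamic pair interpolates between the static and fast limits", {
  pd <- sample_pda_bins(data.frame(R_mean = c(60, 40), R_sigma = 2),
                        areas = c(0.5, 0.5), n_bins = 1500, seed = 3)
  tabs <- pda_precompute_tables(pd)
  T <- pd$sets[[1]]$duration
  states <- data.frame(R_mean = c(60, 40), R_sigma = 2)
  norm1 <- function(h) h / sum(h)

  ## slow limit: tau_ex = 1000 T reproduces the two-static-state histogram
  kslow <- 1 / (1000 * T)
  h_slow <- pda_expected_histogram(pd, list(
    states = states, areas = 1, pair = c(1, 2), R0 = 49,
    k12 = 0.5 * kslow, k21 = 0.5 * kslow), tabs)$expected[[1]]
  h_static <- pda_expected_histogram(pd, list(
    states = states, areas = c(0.5, 0.5), R0 = 49), tabs)$expected[[1]]
  expect_lt(max(abs(norm1(h_slow) - norm1(h_static))), 0.005)

  ## fast limit: tau_ex = T/1000 reproduces one state at the average eps
  kfast <- 1000 / T
  h_fast <- pda_expected_histogram(pd, list(
    states = states, areas = 1, pair = c(1, 2), R0 = 49,
    k12 = 0.5 * kfast, k21 = 0.5 * kfast), tabs)$expected[[1]]
  eps_avg <- mean(vapply(1:2, function(s) mfdburst:::gaussian_mean_eps(
    c(states$R_mean[s], states$R_sigma[s]), 49, pd$corrections), 0))
  ## single-state histogram at the average acceptor probability
  tab <- tabs[[1]]
  h_one <- mfdburst:::pda_table_column(tab, eps_avg)
  h_one <- h_one / sum(h_one) * sum(h_fast)
  expect_lt(max(abs(norm1(h_fast) - norm1(h_one))), 0.01)
})

test_that("the forward model is chi-square consistent with its own draws", {
  states <- data.frame(R_mean = c(62, 49, 39), R_sigma = 3)
  k12 <- 0.894 / 390e-6; k21 <- 0.106 / 390e-6
  pd <- sample_pda_bins(states, areas = c(0.15, 0.85), pair = c(2, 3),
                        k12 = k12, k21 = k21, n_bins = 10000,
                        bg_rate = 1000, seed = 4)
  tabs <- pda_precompute_tables(pd)
  model <- list(states = states, areas = c(0.15, 0.85), pair = c(2, 3),
                R0 = 49, k12 = k12, k21 = k21)
  res <- pda_expected_histogram(pd, model, tabs)
  expect_gt(res$chi2_red, 0.7)
  expect_lt(res$chi2_red, 1.4)
})

test_that("fitting a single-state dataset leaves no room for a second state", {
  states1 <- data.frame(R_mean = 49, R_sigma = 2)
  pd <- sample_pda_bins(states1, areas = 1, n_bins = 4000, seed = 5)
  fit <- fit_pda(pd, states_init = data.frame(R_mean = c(60, 45), R_sigma = 2),
                 pair = NULL, restarts = 3, maxit = 300, seed = 1)
  expect_lt(min(fit$conditions[[1]]$areas), 0.05)
})

test_that("areas and exchange ratio are recovered from model-drawn bins", {
  states <- data.frame(R_mean = c(62, 49, 39), R_sigma = 3)
  k12 <- 0.894 / 390e-6; k21 <- 0.106 / 390e-6
  pd <- sample_pda_bins(states, areas = c(0.15, 0.85), pair = c(2, 3),
                        k12 = k12, k21 = k21, n_bins = 10000,
                        T = c(0.5e-3, 1e-3, 2e-3), bg_rate = 500, seed = 6)
  fit <- fit_pda(pd, states_init = data.frame(R_mean = c(62, 49, 39),
                                              R_sigma = 3),
                 pair = c(2, 3), tau_ex_s = 390e-6,
                 restarts = 3, maxit = 400, seed = 2)
  pops <- fit$conditions[[1]]$populations
  expect_lt(abs(pops[3] - 0.76), 0.05)
  expect_lt(abs(pops[1] - 0.15), 0.05)
  ## k12/k21 ratio within 20 %
  expect_lt(abs(fit$conditions[[1]]$k12 / fit$conditions[[1]]$k21 -
                  k12 / k21) / (k12 / k21), 0.2)
})
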