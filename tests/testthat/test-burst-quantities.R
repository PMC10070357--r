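test_that("corrected E and S evaluate the closed-form expressions", {
  cr <- correction_set(ct = 0.0059, de = 0.024, gamma = 0.69, beta = 1.9)
  q <- compute_burst_quantities(
    data.frame(S_BB = 100, S_BR = 100, S_RR = 50), 0, cr)
  num <- 100 - 0.0059 * 100 - 0.024 * 50
  expect_equal(q$E, num / (0.69 * 100 + num))
  expect_equal(q$E, 0.5874, tolerance = 1e-4)
  expect_equal(q$S, (0.69 * 100 + num) / (0.69 * 100 + num + 50 / 1.9))

  idc <- identity_corrections()
  expect_equal(compute_burst_quantities(
    data.frame(S_BB = 50, S_BR = 0, S_RR = 10), 0, idc)$E, 0)
  expect_equal(compute_burst_quantities(
    data.frame(S_BB = 0, S_BR = 80, S_RR = 40), 0, idc)$E, 1)
  ## zero denominators give NA markers, not errors
  q0 <- compute_burst_quantities(data.frame(S_BB = 0, S_BR = 0, S_RR = 0), 0, idc)
  expect_true(is.na(q0$E) && is.na(q0$PR))
})

test_that("background estimation is count over time with burst excision", {
  n <- 500
  t_s <- seq(0.01, 9.99, length.out = n)
  ps <- photon_stream(floor(t_s * 26.67e6), rep(3L, n), rep("Bpar", n),
                      duration_s = 10, windows = gate_windows())
  bg <- estimate_background(ps)
  expect_equal(unname(bg[["BBpar"]]), 50)
  expect_equal(unname(bg[["RRperp"]]), 0)

  ## excising a fake burst removes its photons and time
  fake <- data.frame(i_start = 1L, i_end = 100L,
                     duration_s = t_s[100] - t_s[1])
  bg2 <- estimate_background(ps, fake)
  expect_equal(unname(bg2[["BBpar"]]), 400 / (10 - fake$duration_s))
})

test_that("E and S are unbiased for static molecules under true corrections", {
  cr <- correction_set()  # gamma 0.69, beta 1.9, zero background
  cfg <- sim_config(corrections = cr)
  for (E_true in c(0.2, 0.5, 0.8)) {
    sc <- kinetic_scheme(data.frame(label = "S", E = E_true, R_sigma = 0))
    ps <- simulate_bursts(150, sc, cfg, min_photons = 80,
                          seed = round(1000 * E_true))
    bt <- analyze_bursts(ps, find_bursts(ps), cr,
                         lifetimes = FALSE, cde_scores = FALSE)
    sem <- stats::sd(bt$E) / sqrt(nrow(bt))
    expect_lt(abs(mean(bt$E) - E_true), 3.5 * sem + 0.005)
    expect_lt(abs(mean(bt$S) - 0.5), 0.02)
  }
})

test_that("with identity corrections S is independent of E", {
  cfg <- sim_config(corrections = identity_corrections())
  schemes <- lapply(c(0.2, 0.5, 0.8), function(E)
    kinetic_scheme(data.frame(label = "S", E = E, R_sigma = 0)))
  ps <- simulate_bursts(240, schemes, cfg, min_photons = 80, seed = 9)
  bt <- analyze_bursts(ps, find_bursts(ps), identity_corrections(),
                       lifetimes = FALSE, cde_scores = FALSE)
  fit <- stats::lm(S ~ E, data = bt)
  expect_lt(abs(unname(stats::coef(fit)[2])), 0.03)
  expect_equal(mean(bt$S), 0.5, tolerance = 0.02)
})

test_that("burst anisotropy follows its definition", {
  expect_equal(burstwise_anisotropy(100, 100, 1), 0)
  expect_equal(burstwise_anisotropy(80, 0, 1), 1)
  expect_equal(burstwise_anisotropy(120, 100, 0.99),
               (0.99 * 120 - 100) / (0.99 * 120 + 200))
  expect_true(is.na(burstwise_anisotropy(0, 0, 1)))
})

test_that("species selection applies the printed windows exactly", {
  base <- data.frame(alex_2cde = 10, E = 0.5, S = 0.5, tau_D_ns = 3,
                     tau_A_ns = 1.7, r_D = 0.2, r_A = 0.2)
  expect_equal(select_species(base), "double")
  don <- data.frame(alex_2cde = 30, E = 0.02, S = 0.95, tau_D_ns = 3,
                    tau_A_ns = NA, r_D = 0.2, r_A = NA)
  expect_equal(select_species(don), "donor_only")
  acc <- data.frame(alex_2cde = 30, E = 0.9, S = 0.05, tau_D_ns = NA,
                    tau_A_ns = 2, r_D = NA, r_A = 0.2)
  expect_equal(select_species(acc), "acceptor_only")
  ## boundary cases fail the strict windows
  edge <- base
  edge$S <- 0.85
  expect_equal(select_species(edge), "unclassified")
  edge2 <- base; edge2$alex_2cde <- 15
  expect_equal(select_species(edge2), "unclassified")
  edge3 <- base; edge3$tau_D_ns <- 4.6
  expect_equal(select_species(edge3), "unclassified")
})

test_that("gamma and beta are recovered from the 1/S-vs-E line", {
  cr <- correction_set()
  cfg <- sim_config(corrections = cr)
  Es <- seq(0.15, 0.9, length.out = 6)
  schemes <- lapply(Es, function(E)
    kinetic_scheme(data.frame(label = "S", E = E, R_sigma = 6)))
  fit <- calibration_fixture()$fit
  expect_equal(fit$Omega, 1 + 0.69 * 1.9, tolerance = 0.05)
  expect_lt(abs(fit$gamma - 0.69), 0.05)
  expect_lt(abs(fit$beta - 1.9), 0.15)

  ## identity-calibration limit: Sigma ~ 0, Omega ~ 2
  cfg0 <- sim_config(corrections = identity_corrections())
  ps0 <- simulate_bursts(400, schemes, cfg0, min_photons = 60, seed = 4)
  bt0 <- analyze_bursts(ps0, find_bursts(ps0), identity_corrections(),
                        lifetimes = FALSE)
  fit0 <- fit_correction_factors(bt0, identity_corrections())
  expect_equal(fit0$Omega, 2, tolerance = 0.07)
  expect_lt(abs(fit0$Sigma), 0.1)

  ## degenerate design: a single E value cannot calibrate
  one <- simulate_bursts(150, schemes[[3]], cfg, min_photons = 60, seed = 5)
  bt1 <- analyze_bursts(one, find_bursts(one), cr, lifetimes = FALSE)
  expect_error(fit_correction_factors(bt1, cr), "calibration error")
})
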