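test_that("diffusion weights follow the closed forms for frozen molecules", {
  cfg <- sim_config(D = 0)
  tr0 <- simulate_diffusion(cfg, 1e-3, x0 = c(0, 0, 0))
  expect_true(all(tr0$w == 1))
  tr1 <- simulate_diffusion(cfg, 1e-3, x0 = c(0.5, 0, 0))
  expect_equal(unique(tr1$w), exp(-2))
})

test_that("simulated intensity decorrelates on the diffusion timescale", {
  cfg <- sim_config(D = 100, psf = c(0.5, 0.5, 2), box = c(1.5, 1.5, 4))
  set.seed(14)
  tr <- simulate_diffusion(cfg, 4, x0 = c(0, 0, 0))
  w <- tr$w
  ## autocorrelation time of the intensity vs w_xy^2 / (4 D) = 0.625 ms
  lags <- seq(50e-6, 3e-3, by = 50e-6)
  ac <- vapply(round(lags / cfg$dt), function(k) {
    n <- length(w)
    stats::cor(w[1:(n - k)], w[(k + 1):n])
  }, 0)
  tau_fit <- stats::nls(ac ~ 1 / ((1 + lags / td) * sqrt(1 + lags / (16 * td))),
                        start = list(td = 1e-3))
  expect_equal(unname(stats::coef(tau_fit)["td"]), 0.625e-3, tolerance = 0.2)
})

test_that("emission obeys the no-FRET no-crosstalk limit and backgrounds", {
  cfg <- sim_config(corrections = identity_corrections())
  sc <- kinetic_scheme(data.frame(label = "S", E = 0, R_sigma = 0))
  tr <- list(list(dt = 1e-6, w = rep(1, 20000)))
  set.seed(15)
  ps <- emit_photons(tr, list(simulate_state_trajectory(sc, 0.02)), sc, cfg)
  counts <- gate_counts(ps)
  expect_equal(counts[["BRpar"]] + counts[["BRperp"]], 0)
  expect_gt(counts[["BBpar"]] + counts[["BBperp"]], 0)

  ## background only: rates recovered within Poisson error
  bgcfg <- sim_config(corrections = identity_corrections(
    background = c(BBpar = 1000, BBperp = 1000, BRpar = 1000,
                   BRperp = 1000, RRpar = 1000, RRperp = 1000)))
  sc0 <- kinetic_scheme(data.frame(label = "S", E = 0))
  tr0 <- list(list(dt = 1e-6, w = rep(0, 1000)))
  set.seed(16)
  ## 10 s of background only
  bg <- mfdburst:::emit_background(10, bgcfg)
  expect_equal(length(bg$t_abs), 6e4, tolerance = 0.03)
})

test_that("detected brightness of a centred static molecule matches the config", {
  cfg <- sim_config(corrections = identity_corrections(), brightness = 1e5)
  sc <- kinetic_scheme(data.frame(label = "S", E = 0.5, R_sigma = 0))
  tr <- list(list(dt = 1e-6, w = rep(1, 5e4)))
  set.seed(17)
  ps <- emit_photons(tr, list(simulate_state_trajectory(sc, 0.05)), sc, cfg)
  counts <- gate_counts(ps)
  dex <- sum(counts[1:4])
  ## identity corrections: Dex rate = brightness (E-split leaves total intact)
  expect_equal(dex / 0.05, 1e5, tolerance = 0.05)
  rr <- counts[["RRpar"]] + counts[["RRperp"]]
  expect_equal(rr / 0.05, 1e5, tolerance = 0.05)
})

test_that("identical seeds give identical streams", {
  sc <- scenario_scheme("apo")
  cfg <- sim_config()
  a <- simulate_mfd(cfg, sc$schemes, duration = 0.5, n_molecules = 2,
                    scheme_probs = sc$scheme_probs, seed = 99)
  b <- simulate_mfd(cfg, sc$schemes, duration = 0.5, n_molecules = 2,
                    scheme_probs = sc$scheme_probs, seed = 99)
  expect_identical(a$macrotime, b$macrotime)
  expect_identical(a$nanotime, b$nanotime)
  expect_identical(a$detector, b$detector)

  r1 <- generate_reference_dataset("full_agonist", n_target_bursts = 5,
                                   seed = 5, n_molecules = 2,
                                   config = sim_config(),
                                   max_slabs = 1)
  r2 <- generate_reference_dataset("full_agonist", n_target_bursts = 5,
                                   seed = 5, n_molecules = 2,
                                   config = sim_config(),
                                   max_slabs = 1)
  expect_identical(r1$stream$macrotime, r2$stream$macrotime)
  expect_equal(r1$truth$hf_population, 0.76)
  expect_equal(r1$truth$tau_ex_s, 390e-6)
})

test_that("burst generator recovers the configured state efficiencies", {
  ## two-state dynamic bursts average toward the occupancy-weighted E
  bt <- dynamic_fixture()$bt
  expect_equal(mean(bt$E), 0.55, tolerance = 0.03)
})
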