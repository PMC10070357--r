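test_that("cone semi-angle inverts the wobbling-in-a-cone relation", {
  expect_equal(cone_semiangle(c(0.12, 0.16, 0.22, 0.23), digits = 0),
               c(49, 43, 35, 34))
  expect_equal(cone_semiangle(0.4), 0)
  expect_error(cone_semiangle(0.5), "r0_star")
  ## strictly decreasing in rp, and exact round trip through the relation
  rp <- seq(0.01, 0.39, by = 0.01)
  th <- cone_semiangle(rp, digits = 10)
  expect_true(all(diff(th) < 0))
  cth <- cos(th * pi / 180)
  expect_equal((cth * (1 + cth) / 2)^2 * 0.4, rp, tolerance = 1e-10)
})

test_that("anisotropy decay from photons reproduces the generating model", {
  truth <- list(r0 = 0.37, rp = 0.14, rho_F = 1, rho_p = 60)
  sim <- simulate_polarized_decay(4e5, tau_ns = 3.8, r0 = truth$r0,
                                  rp = truth$rp, rho_F_ns = truth$rho_F,
                                  rho_p_ns = truth$rho_p, G = 0.99, seed = 5)
  nano <- as.integer(sim$t_ns / (37.5 / 4096))
  det <- ifelse(sim$parallel, "Bpar", "Bperp")
  ps <- photon_stream(seq_along(nano) * 10, nano, det, windows = gate_windows())
  cr <- correction_set(G_B = 0.99)
  dec <- decay_from_photons(ps, dye = "donor", corrections = cr,
                            bin_width_ns = 0.15)
  ## pointwise within the shot-noise envelope at early times
  model_r <- function(t) ((truth$r0 - truth$rp) * exp(-t / truth$rho_F) +
                            truth$rp) * exp(-t / truth$rho_p)
  early <- dec[dec$t_ns >= 0 & dec$t_ns < 8, ]
  resid <- early$r - model_r(early$t_ns)
  expect_lt(mean(abs(resid)), 0.02)

  fit <- fit_anisotropy_decay(dec)
  expect_lt(abs(fit$r0 - truth$r0), 0.05)
  expect_lt(abs(fit$rp - truth$rp), 0.02)
  expect_lt(abs(fit$rho_F_ns - truth$rho_F), 0.5)
})

test_that("noiseless decay fit is exact and degenerate cases are flagged", {
  t <- seq(0, 15, by = 0.05)
  r <- ((0.37 - 0.14) * exp(-t / 1) + 0.14) * exp(-t / 60)
  dec <- data.frame(t_ns = t, r = r, weight = rep(1000, length(t)))
  fit <- fit_anisotropy_decay(dec)
  expect_equal(fit$r0, 0.37, tolerance = 1e-3)
  expect_equal(fit$rp, 0.14, tolerance = 1e-3)
  expect_equal(fit$rho_F_ns, 1, tolerance = 1e-2)
  expect_equal(fit$rho_p_ns, 60, tolerance = 1)
  expect_false(fit$rho_p_at_bound)

  ## constant r(t): fast time unidentifiable
  dec2 <- data.frame(t_ns = t, r = rep(0.2, length(t)),
                     weight = rep(1000, length(t)))
  fit2 <- fit_anisotropy_decay(dec2)
  expect_equal(fit2$rp, 0.2, tolerance = 0.01)
  expect_false(fit2$identifiable)

  ## effectively infinite slow time runs into the bound and is reported so
  r3 <- ((0.37 - 0.14) * exp(-t / 1) + 0.14)
  dec3 <- data.frame(t_ns = t, r = r3, weight = rep(1000, length(t)))
  fit3 <- fit_anisotropy_decay(dec3, rho_p_bounds_ns = c(10, 1000))
  expect_true(fit3$rho_p_at_bound)
})

test_that("time-integrated r(t) equals the steady-state anisotropy", {
  sim <- simulate_polarized_decay(2e5, seed = 8, G = 1.13)
  nano <- as.integer((18 + sim$t_ns) / (37.5 / 4096))   # acceptor window
  det <- ifelse(sim$parallel, "Rpar", "Rperp")
  ps <- photon_stream(seq_along(nano) * 10, nano, det, windows = gate_windows())
  cr <- correction_set(G_R = 1.13)
  dec <- decay_from_photons(ps, dye = "acceptor", corrections = cr)
  r_int <- sum(dec$r * dec$weight) / sum(dec$weight)
  Fpar <- sum(dec$F_par); Fperp <- sum(dec$F_perp)
  r_ss <- (1.13 * Fpar - Fperp) / (1.13 * Fpar + 2 * Fperp)
  expect_equal(r_int, r_ss, tolerance = 1e-6)
})
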