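test_that("MLE reduces to the sample mean for a wide window", {
  fit <- burstwise_lifetime_mle(c(1, 2, 3) * 1e-9, window_s = 1e-6,
                                min_photons = 3)
  expect_equal(fit$tau_ns, 2, tolerance = 1e-3)
})

test_that("MLE matches a grid-search oracle on truncated data", {
  set.seed(42)
  W <- 18e-9
  tau_true <- 3e-9
  ## truncated exponential draws
  u <- runif(1e4)
  t <- -tau_true * log(1 - u * (1 - exp(-W / tau_true)))
  fit <- burstwise_lifetime_mle(t, W)
  expect_equal(fit$tau_ns, 3, tolerance = 0.05)

  ## independent grid-search oracle over the same likelihood
  grid <- seq(2, 4, by = 0.002)
  nll <- vapply(grid, function(tau_ns) {
    tau <- tau_ns * 1e-9
    -sum(log(exp(-t / tau) / (tau * (1 - exp(-W / tau)))))
  }, 0)
  expect_equal(fit$tau_ns, grid[which.min(nll)], tolerance = 0.01)
})

test_that("background fraction enters the likelihood", {
  set.seed(7)
  W <- 18e-9
  tau_true <- 2e-9
  n_f <- 8000; n_b <- 2000
  u <- runif(n_f)
  t <- c(-tau_true * log(1 - u * (1 - exp(-W / tau_true))), runif(n_b, 0, W))
  biased <- burstwise_lifetime_mle(t, W, bg_fraction = 0)
  corrected <- burstwise_lifetime_mle(t, W, bg_fraction = 0.2)
  expect_gt(biased$tau_ns, corrected$tau_ns)
  expect_equal(corrected$tau_ns, 2, tolerance = 0.06)
})

test_that("degenerate inputs are flagged", {
  few <- burstwise_lifetime_mle(rep(1e-9, 5), 18e-9)
  expect_true(is.na(few$tau_ns))
  edge <- burstwise_lifetime_mle(rep(17.9e-9, 50), 18e-9)
  expect_true(edge$boundary)
})

test_that("burst-wise donor and acceptor lifetimes recover the simulation truth", {
  ps <- with_cache("static500", static_burst_stream(120, seed = 11))
  bt <- analyze_bursts(ps, find_bursts(ps), identity_corrections(),
                       cde_scores = FALSE)
  ## E ~ 0.5 with sigma = 6 A linker: donor photons weight low-E draws,
  ## tau_D above tau_D0 * (1 - <E>) is expected; check a generous band
  expect_gt(mean(bt$tau_D_ns, na.rm = TRUE), 1.7)
  expect_lt(mean(bt$tau_D_ns, na.rm = TRUE), 2.4)
  expect_equal(mean(bt$tau_A_ns, na.rm = TRUE), 1.7, tolerance = 0.05)
})
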