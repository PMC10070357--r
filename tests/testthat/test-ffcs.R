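test_that("filters solve the weighted unmixing exactly on hand examples", {
  ## orthogonal patterns: identity filters
  f <- compute_filters(list(p_lf = c(1, 0), p_hf = c(0, 1)), total = c(5, 5))
  expect_equal(unname(f$f_lf), c(1, 0))
  expect_equal(unname(f$f_hf), c(0, 1))

  ## three-channel example against hand linear algebra
  f2 <- compute_filters(list(p_lf = c(0.5, 0.5, 0), p_hf = c(0, 0.5, 0.5)),
                        total = c(10, 20, 10))
  expect_equal(unname(f2$f_lf), c(1.5, 0.5, -0.5))
  expect_equal(unname(f2$f_hf), c(-0.5, 0.5, 1.5))
  expect_equal(sum(f2$f_lf * c(10, 20, 10)), 20)
  expect_equal(sum(f2$f_hf * c(10, 20, 10)), 20)
  ## reconstruction: the filters of a pattern-consistent mixture sum to one
  expect_equal(unname(f2$f_lf + f2$f_hf), rep(1, 3))

  ## collinear patterns are a conditioning error
  expect_error(compute_filters(list(p_lf = c(0.5, 0.5), p_hf = c(0.5, 0.5)),
                               total = c(10, 10)),
               "conditioning")
})

test_that("filter-weighted sums are unbiased species-photon counts", {
  set.seed(30)
  nb <- 16
  p1 <- rep(1 / nb, nb)                      # flat low-FRET pattern
  p2 <- dexp(seq(0, 3, length.out = nb)); p2 <- p2 / sum(p2)
  for (rep_i in 1:5) {
    n1 <- 4000; n2 <- 6000
    counts <- tabulate(c(sample.int(nb, n1, TRUE, p1),
                         sample.int(nb, n2, TRUE, p2)), nb)
    f <- compute_filters(list(p_lf = p1, p_hf = p2), total = counts)
    est1 <- sum(f$f_lf * counts); est2 <- sum(f$f_hf * counts)
    ## generous 3-sigma-style bound on the unmixing error
    expect_lt(abs(est1 - n1), 3 * sqrt(n1 + n2))
    expect_lt(abs(est2 - n2), 3 * sqrt(n1 + n2))
  }
})

test_that("species patterns reflect the lifetime-FRET relation", {
  ps <- with_cache("patterns_mix", {
    schemes <- lapply(c(0.2, 0.8), function(E)
      kinetic_scheme(data.frame(label = "S", E = E, R_sigma = 6)))
    simulate_bursts(160, schemes, sim_config(corrections = identity_corrections()),
                    min_photons = 80, seed = 31)
  })
  bt <- analyze_bursts(ps, find_bursts(ps), identity_corrections(),
                       lifetimes = FALSE, cde_scores = FALSE)
  pat <- build_species_patterns(ps, bt, n_bins = 32)
  expect_equal(sum(pat$p_lf), 1, tolerance = 1e-9)
  expect_equal(sum(pat$p_hf), 1, tolerance = 1e-9)
  ## donor-gate (stacked channels 1..64) mean microtime bin: the high-FRET
  ## species decays faster
  donor_bins <- rep(1:32, 2)
  lf_donor <- pat$p_lf[1:64]; hf_donor <- pat$p_hf[1:64]
  expect_gt(sum(donor_bins * lf_donor) / sum(lf_donor),
            sum(donor_bins * hf_donor) / sum(hf_donor))
  ## and carries a smaller share in the acceptor gates
  expect_lt(sum(pat$p_lf[65:128]), sum(pat$p_hf[65:128]))
})

test_that("the correlator matches the brute-force oracle", {
  for (seed in c(1, 2, 3)) {
    set.seed(seed)
    ## small two-species burst stream
    schemes <- lapply(c(0.2, 0.8), function(E)
      kinetic_scheme(data.frame(label = "S", E = E, R_sigma = 0)))
    ps <- simulate_bursts(6, schemes, sim_config(corrections = identity_corrections()),
                          min_photons = 60, mean_duration_s = 1.5e-3,
                          seed = 40 + seed)
    bt <- analyze_bursts(ps, find_bursts(ps), identity_corrections(),
                         lifetimes = FALSE, cde_scores = FALSE)
    pat <- build_species_patterns(ps, bt, E_low = 0.5, E_high = 0.5)
    j <- stacked_channel(ps, 32)
    filt <- compute_filters(pat, tabulate(j[!is.na(j)], 128))
    got <- filtered_correlation(ps, filt, bt, bin_s = 20e-6, n_casc = 6,
                                segments = 2)
    want <- oracle_filtered_correlation(ps, filt, bt, bin_s = 20e-6, n_casc = 6)
    expect_equal(got$lag_s, want$lag_s)
    expect_equal(got$G, want$G, tolerance = 1e-10, info = paste("seed", seed))
  }
})

test_that("a homogeneous Poisson stream is uncorrelated", {
  set.seed(33)
  n <- 20000
  t_s <- sort(runif(n, 0, 2))
  det <- sample(c("Bpar", "Bperp", "Rpar", "Rperp"), n, TRUE)
  nano <- sample.int(1900L, n, replace = TRUE) - 1L
  ps <- photon_stream(floor(t_s * 26.67e6), nano, det, windows = gate_windows())
  bt <- data.frame(t_start_s = seq(0.1, 1.9, 0.2), t_end_s = seq(0.15, 1.95, 0.2))
  pat <- list(p_lf = rep(1 / 128, 128),
              p_hf = dexp(seq(0, 2, length.out = 128)))
  pat$p_hf <- pat$p_hf / sum(pat$p_hf)
  filt <- compute_filters(pat, rep(n / 128, 128))
  cr <- filtered_correlation(ps, filt, bt, bin_s = 1e-4, n_casc = 6)
  ## no systematic correlation: standardized G consistent with zero
  z <- cr$G / cr$sem
  z <- z[is.finite(z)]
  expect_lt(abs(mean(z)), 0.75)
  expect_lt(mean(abs(z) > 4), 0.1)
})

test_that("the diffusion model has its closed-form limits", {
  expect_equal(ffcs_diffusion(0, N = 2, tau_diff = 1e-3), 1 / (sqrt(8) * 2))
  ## large-lag limit decays to zero, so G tends to y0
  expect_lt(ffcs_diffusion(10, N = 2, tau_diff = 1e-3), 1e-4)
})

test_that("fitting a model-generated curve recovers the parameters", {
  set.seed(34)
  lag <- exp(seq(log(4e-6), log(0.1), length.out = 60))
  truth <- list(N = 0.05, tau_diff = 1.5e-3, A = 0.8, tau = 390e-6, y0 = 0.02)
  g <- ffcs_diffusion(lag, truth$N, truth$tau_diff) *
    (1 - truth$A * exp(-lag / truth$tau)) + truth$y0
  for (i in 1:3) {
    noisy <- g + rnorm(length(g), 0, 0.02 * max(g))
    cv <- data.frame(lag_s = lag, G = noisy, sd = 0.02 * max(g),
                     sem = 0.02 * max(g))
    fit <- fit_ffcs_model(list(x = cv), n_terms = 1)
    expect_lt(abs(fit$conditions$x$tau - truth$tau) / truth$tau, 0.35)
    expect_true(fit$conditions$x$tau_ci[1] < truth$tau &&
                  truth$tau < fit$conditions$x$tau_ci[2])
  }
  expect_equal(ffcs_diffusion(0, truth$N, truth$tau_diff), 1 / (sqrt(8) * truth$N))
})

test_that("longer ground-truth exchange gives a longer fitted time", {
  set.seed(35)
  lag <- exp(seq(log(4e-6), log(0.1), length.out = 60))
  fit_tau <- vapply(c(2e-4, 8e-4), function(tau_ex) {
    g <- ffcs_diffusion(lag, 0.05, 1.5e-3) * (1 - 0.8 * exp(-lag / tau_ex))
    noisy <- g + rnorm(length(g), 0, 0.02 * max(g))
    cv <- data.frame(lag_s = lag, G = noisy, sd = 1, sem = 0.02 * max(g))
    fit_ffcs_model(list(x = cv), n_terms = 1)$conditions$x$tau
  }, 0)
  expect_gt(fit_tau[2], fit_tau[1])
})
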