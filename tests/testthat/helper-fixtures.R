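## shared fixtures, built once per test run and cached

fixture_env <- new.env(parent = emptyenv())

with_cache <- function(key, expr) {
  if (is.null(fixture_env[[key]])) fixture_env[[key]] <- force(expr)
  fixture_env[[key]]
}

## a small photon stream with known structure
tiny_stream <- function(n = 1000, seed = 1) {
  set.seed(seed)
  macro <- sort(sample.int(26e6, n))
  nano <- sample.int(4096L, n) - 1L
  det <- sample(c("Bpar", "Bperp", "Rpar", "Rperp"), n, replace = TRUE)
  assign_pie_gates(photon_stream(macro, nano, det), gate_windows())
}

## static-burst dataset at a fixed true E, identity corrections, no background
static_burst_stream <- function(n_bursts, E_true = 0.5, seed = 1,
                                min_photons = 80, corrections = identity_corrections(),
                                sigma = 6) {
  sc <- kinetic_scheme(data.frame(label = "S", E = E_true, R_sigma = sigma))
  cfg <- sim_config(corrections = corrections)
  simulate_bursts(n_bursts, sc, cfg, min_photons = min_photons, seed = seed)
}

## two-state dynamic bursts (E 0.3 <-> 0.8, tau_ex 390 us)
dynamic_burst_stream <- function(n_bursts, seed = 1, tau_ex = 390e-6,
                                 E = c(0.3, 0.8), min_photons = 80) {
  k <- 0.5 / tau_ex
  sc <- kinetic_scheme(data.frame(label = c("A", "B"), E = E, R_sigma = 6),
                       rates = matrix(c(0, k, k, 0), 2, 2, byrow = TRUE))
  cfg <- sim_config(corrections = identity_corrections())
  simulate_bursts(n_bursts, sc, cfg, min_photons = min_photons,
                  mean_duration_s = 3e-3, seed = seed)
}

## brute-force burst search oracle: same rule, O(n^2)
find_bursts_oracle <- function(ps, window_s = 500e-6, min_per_window = 5,
                               min_photons = 50, duration_range = c(0, 20e-3)) {
  t <- ps$macrotime
  n <- length(t)
  if (n == 0)
    return(data.frame(i_start = integer(0), i_end = integer(0)))
  W <- window_s / 2 * ps$sync_rate_hz
  Wfull <- window_s * ps$sync_rate_hz
  eligible <- vapply(seq_len(n), function(i)
    sum(t >= t[i] - W & t <= t[i] + W) >= min_per_window, TRUE)
  out <- list()
  i <- 1L
  while (i <= n) {
    if (!eligible[i]) { i <- i + 1L; next }
    j <- i
    while (j < n && eligible[j + 1L] && (t[j + 1L] - t[j]) <= Wfull) j <- j + 1L
    np <- j - i + 1L
    dur <- (t[j] - t[i]) / ps$sync_rate_hz
    if (np >= min_photons && dur >= duration_range[1] && dur <= duration_range[2])
      out[[length(out) + 1L]] <- data.frame(i_start = i, i_end = j)
    i <- j + 1L
  }
  if (!length(out)) return(data.frame(i_start = integer(0), i_end = integer(0)))
  do.call(rbind, out)
}

## ---- shared expensive computations (built once, reused across files) -------

static_fixture <- function() with_cache("static_fix", {
  ps <- static_burst_stream(260, E_true = 0.5, seed = 21, min_photons = 100)
  bt <- analyze_bursts(ps, find_bursts(ps), identity_corrections(),
                       cde_scores = FALSE)
  list(ps = ps, bt = bt, pd = burst_photon_data(ps, find_bursts(ps)))
})

dynamic_fixture <- function() with_cache("dynamic_fix", {
  ps <- dynamic_burst_stream(260, seed = 22, min_photons = 100)
  bt <- analyze_bursts(ps, find_bursts(ps), identity_corrections(),
                       cde_scores = FALSE)
  list(ps = ps, bt = bt, pd = burst_photon_data(ps, find_bursts(ps)))
})

cde_null_static <- function() with_cache("cde_null_static", {
  f <- static_fixture()
  fret_2cde_null_test(f$pd, f$bt$E, n_groups = 10, min_bursts = 50,
                      repetitions = 300, seed = 1)
})

cde_null_dynamic <- function() with_cache("cde_null_dynamic", {
  f <- dynamic_fixture()
  fret_2cde_null_test(f$pd, f$bt$E, n_groups = 10, min_bursts = 50,
                      repetitions = 300, seed = 1)
})

bva_static <- function() with_cache("bva_static", {
  bva(static_fixture()$pd, n_groups = 10, min_bursts = 40, repetitions = 400,
      corrections = identity_corrections(), seed = 2)
})

bva_dynamic <- function() with_cache("bva_dynamic", {
  bva(dynamic_fixture()$pd, n_groups = 10, min_bursts = 40, repetitions = 400,
      corrections = identity_corrections(), seed = 2)
})

shift_static <- function() with_cache("shift_static", {
  f <- static_fixture()
  lifetime_shift_test(f$ps, f$bt, tau_D0_ns = 3.8, sigma = 6, n_groups = 10,
                      min_bursts = 50, repetitions = 100, seed = 1)
})

shift_dynamic <- function() with_cache("shift_dynamic", {
  f <- dynamic_fixture()
  lifetime_shift_test(f$ps, f$bt, tau_D0_ns = 3.8, sigma = 6, n_groups = 10,
                      min_bursts = 50, repetitions = 100, seed = 1)
})

calibration_fixture <- function() with_cache("calibration_fix", {
  cr <- correction_set()
  cfg <- sim_config(corrections = cr)
  Es <- seq(0.15, 0.9, length.out = 6)
  schemes <- lapply(Es, function(E)
    kinetic_scheme(data.frame(label = "S", E = E, R_sigma = 6)))
  ps <- simulate_bursts(600, schemes, cfg, min_photons = 60, seed = 3)
  bt <- analyze_bursts(ps, find_bursts(ps), cr, lifetimes = FALSE)
  list(bt = bt, fit = fit_correction_factors(bt, cr))
})
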