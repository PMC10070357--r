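#' Simulate isolated single-molecule bursts
#'
#' A lightweight burst-level generator: each burst is a constant-intensity
#' dwell of one molecule in the spot (uniform photon arrival times), with the
#' full emission model of [emit_photons()] -- per-photon linker distance
#' draws, crosstalk, direct excitation, gamma/beta detection factors,
#' lifetimes, polarization. Bursts are separated by silent gaps, so the
#' sliding-window burst search recovers them exactly. This is the generator
#' of choice for shot-noise null calibrations (FRET-2CDE, BVA, lifetime-shift
#' test) and correction-factor recovery, where diffusion-path realism is not
#' the point.
#'
#' @param n_bursts number of bursts.
#' @param scheme a [kinetic_scheme()]; one state gives static bursts, two
#'   states give in-burst exchange. A list of schemes (with `scheme_probs`)
#'   draws a scheme per burst.
#' @param config a [sim_config()]; `brightness` sets the in-burst intensity.
#'   Background rates in `config$corrections$background` apply over the whole
#'   stream (default configs for this generator usually set them to zero).
#' @param mean_duration_s mean burst duration (gamma-distributed, shape 3).
#' @param min_photons redraw bursts until at least this many donor-excitation
#'   photons are detected.
#' @param gap_s silent gap between consecutive bursts.
#' @param scheme_probs per-burst scheme probabilities when `scheme` is a list.
#' @param seed integer seed.
#' @return a [photon_stream()]; the true burst intervals are attached as
#'   attribute `"true_bursts"` (data.frame with `t_start`, `t_end`, `scheme`).
#' @export
simulate_bursts <- function(n_bursts, scheme, config = sim_config(),
                            mean_duration_s = 2e-3, min_photons = 50,
                            gap_s = 20e-3, scheme_probs = NULL, seed = NULL) {
  stopifnot(n_bursts >= 1)
  if (!is.null(seed)) set.seed(seed)
  schemes <- if (inherits(scheme, "kinetic_scheme")) list(scheme) else scheme
  if (is.null(scheme_probs)) scheme_probs <- rep(1 / length(schemes), length(schemes))
  parts <- vector("list", n_bursts)
  truth <- data.frame(t_start = numeric(n_bursts), t_end = numeric(n_bursts),
                      scheme = integer(n_bursts))
  t_cursor <- gap_s
  dt <- config$dt
  for (b in seq_len(n_bursts)) {
    isc <- sample.int(length(schemes), 1, prob = scheme_probs)
    sc <- schemes[[isc]]
    repeat {
      d <- stats::rgamma(1, shape = 3, scale = mean_duration_s / 3)
      m <- max(2L, round(d / dt))
      path <- simulate_state_trajectory(sc, m * dt)
      ph <- emit_photons_one(rep.int(1, m), dt, t_cursor, path, sc, config)
      if (length(ph$t_abs) >= min_photons && count_dex(ph, config) >= min_photons) break
    }
    parts[[b]] <- ph
    truth$t_start[b] <- t_cursor
    truth$t_end[b] <- t_cursor + m * dt
    truth$scheme[b] <- isc
    t_cursor <- t_cursor + m * dt + gap_s
  }
  if (any(config$corrections$background > 0)) {
    parts[[length(parts) + 1L]] <-
      emit_background(t_cursor, config)
  }
  ps <- assemble_stream(parts, t_cursor, config)
  attr(ps, "true_bursts") <- truth
  ps
}

# donor-excitation photon count of an emission part
count_dex <- function(ph, config) {
  res <- 1 / (config$sync_rate_hz * config$n_tcspc_bins)
  sum(ph$nanotime * res >= config$windows$donor[1] &
        ph$nanotime * res < config$windows$donor[2])
}

#' Kinetic schemes of the four study scenarios
#'
#' Builds the three-state scheme used by the reference datasets: a static
#' low-FRET state (E = 0.20) that never exchanges, plus a medium-FRET
#' (E = 0.50) / high-FRET (E = 0.80) pair exchanging with relaxation time
#' `tau_ex`. The high-FRET occupancy and exchange time depend on the
#' scenario: 0.20 of all molecules for `apo` and `antagonist` (exchange
#' effectively frozen at 200 ms), 0.56 for `partial_agonist` and 0.76 for
#' `full_agonist` (both exchanging at 390 us). A fixed fraction `lf_fraction`
#' of molecules sits in the static low-FRET state.
#'
#' @param scenario one of `"apo"`, `"antagonist"`, `"partial_agonist"`,
#'   `"full_agonist"`.
#' @param lf_fraction fraction of molecules locked in the low-FRET state.
#' @param R0 Foerster distance (Angstrom).
#' @param linker_sigma apparent-distance (linker) width per state (Angstrom).
#' @return list with `schemes` (list of two [kinetic_scheme()]: static LF,
#'   dynamic MF/HF pair), `scheme_probs`, and the ground-truth summary
#'   (`hf_population`, `mf_population`, `lf_fraction`, `tau_ex_s`,
#'   `p_hf_pair`, rates).
#' @export
scenario_scheme <- function(scenario = c("apo", "antagonist", "partial_agonist",
                                         "full_agonist"),
                            lf_fraction = 0.15, R0 = 49, linker_sigma = 6) {
  scenario <- match.arg(scenario)
  hf_pop <- switch(scenario, apo = 0.20, antagonist = 0.20,
                   partial_agonist = 0.56, full_agonist = 0.76)
  tau_ex <- if (scenario %in% c("partial_agonist", "full_agonist")) 390e-6 else 200e-3
  p_hf <- hf_pop / (1 - lf_fraction)
  k_mh <- p_hf / tau_ex
  k_hm <- (1 - p_hf) / tau_ex
  lf <- kinetic_scheme(data.frame(label = "LF", E = 0.20, R_sigma = linker_sigma),
                       R0 = R0)
  pair <- kinetic_scheme(data.frame(label = c("MF", "HF"), E = c(0.50, 0.80),
                                    R_sigma = linker_sigma),
                         rates = matrix(c(0, k_mh, k_hm, 0), 2, 2, byrow = TRUE),
                         R0 = R0)
  list(schemes = list(lf, pair),
       scheme_probs = c(lf_fraction, 1 - lf_fraction),
       truth = list(scenario = scenario, hf_population = hf_pop,
                    mf_population = 1 - lf_fraction - hf_pop,
                    lf_fraction = lf_fraction, tau_ex_s = tau_ex,
                    p_hf_pair = p_hf, k_mh = k_mh, k_hm = k_hm,
                    E_states = c(LF = 0.20, MF = 0.50, HF = 0.80),
                    R0 = R0, linker_sigma = linker_sigma))
}

#' Generate a reference dataset for one ligand scenario
#'
#' Simulates the diffusion-based acquisition for one of the four study
#' conditions until the all-photon burst search yields at least
#' `n_target_bursts` bursts, and returns the stream together with the
#' ground-truth record (state efficiencies, populations, exchange rates,
#' correction truths, seed).
#'
#' @param scenario see [scenario_scheme()].
#' @param n_target_bursts stop once this many bursts are found.
#' @param seed integer seed.
#' @param config a [sim_config()].
#' @param n_molecules concurrent molecules per simulation slab; the default
#'   makes `n_molecules * lf_fraction` integral, so the stratified scheme
#'   allocation realises the nominal composition exactly in every slab.
#' @param burst_opts arguments passed to [find_bursts()] for the stopping
#'   rule.
#' @param max_slabs safety cap on simulation slabs.
#' @param path optional basename; writes `<path>.tsv` (photons) and
#'   `<path>.json` (ground truth).
#' @return list with `stream` ([photon_stream()]) and `truth` (list).
#' @export
generate_reference_dataset <- function(scenario, n_target_bursts = 3000,
                                       seed = 1, config = sim_config(),
                                       n_molecules = 20,
                                       burst_opts = list(),
                                       max_slabs = 15, path = NULL) {
  set.seed(seed)
  sc <- scenario_scheme(scenario)
  slab_s <- 10
  stream <- NULL
  n_found <- 0
  total_s <- 0
  for (slab in seq_len(max_slabs)) {
    piece <- simulate_mfd(config, sc$schemes, duration = slab_s,
                          n_molecules = n_molecules,
                          scheme_probs = sc$scheme_probs)
    stream <- if (is.null(stream)) piece else concat_streams(stream, piece)
    total_s <- total_s + slab_s
    bt <- do.call(find_bursts, c(list(stream), burst_opts))
    n_found <- nrow(bt)
    if (n_found >= n_target_bursts) break
    rate <- max(n_found / total_s, 1e-3)
    slab_s <- min(60, max(5, ceiling(1.15 * (n_target_bursts - n_found) / rate)))
  }
  truth <- c(sc$truth,
             list(seed = seed, n_bursts_found = n_found,
                  duration_s = total_s, n_molecules = n_molecules,
                  brightness = config$brightness,
                  corrections = unclass(config$corrections)[
                    c("ct", "de", "gamma", "beta", "G_B", "G_R")],
                  background_hz = as.list(config$corrections$background)))
  if (!is.null(path)) {
    write_photons(stream, paste0(path, ".tsv"))
    jsonlite::write_json(truth, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  list(stream = stream, truth = truth)
}

#' Concatenate two photon streams end to end
#' @param a,b [photon_stream()] objects with identical instrument metadata.
#' @param gap_s silent gap inserted between them.
#' @return a [photon_stream()].
#' @export
concat_streams <- function(a, b, gap_s = 0.1) {
  stopifnot(a$sync_rate_hz == b$sync_rate_hz, a$n_tcspc_bins == b$n_tcspc_bins)
  offset <- ceiling((a$duration_s + gap_s) * a$sync_rate_hz)
  ps <- photon_stream(c(a$macrotime, b$macrotime + offset),
                      c(a$nanotime, b$nanotime),
                      DETECTORS[c(a$detector, b$detector)],
                      sync_rate_hz = a$sync_rate_hz,
                      n_tcspc_bins = a$n_tcspc_bins,
                      duration_s = a$duration_s + gap_s + b$duration_s,
                      windows = a$windows)
  ps
}
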