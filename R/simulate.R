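#' Simulation configuration for the photon-stream generator
#'
#' Collects the optical, photophysical and kinetic parameters of the forward
#' Monte-Carlo model: freely diffusing molecules cross a 3D Gaussian
#' excitation/detection spot; the current conformational state sets the FRET
#' efficiency (through an apparent distance draw per photon, the fast-linker
#' limit); photons are emitted in the six PIE gates with rates consistent with
#' the correction factors, so that the corrected-E estimator applied with the
#' true factors is unbiased.
#'
#' @param psf half-widths of the 3D Gaussian spot in micrometres,
#'   `c(wx, wy, wz)`.
#' @param D diffusion coefficient in um^2/s.
#' @param box half-sides of the simulation box in micrometres (reflecting
#'   boundaries); one molecule occupies one box, so the box volume sets the
#'   effective concentration. The default keeps the mean number of
#'   simultaneously excited molecules below 0.1 (single-molecule regime).
#' @param brightness molecular brightness at the spot centre, in detected
#'   donor-scale photons per second.
#' @param tau_D0_ns donor-only fluorescence lifetime (ns).
#' @param tau_A_ns acceptor fluorescence lifetime (ns).
#' @param R0 Foerster distance (Angstrom).
#' @param corrections a [correction_set()] holding the ground-truth ct, de,
#'   gamma, beta, G factors and per-gate background rates.
#' @param r_D,r_A steady-state anisotropies used for the per-photon
#'   polarization draw of donor and acceptor photons.
#' @param blinking `NULL` (default, off) or `list(k_off, k_on)` in 1/s for a
#'   two-state dark model that gates all fluorescence emission off during dark
#'   dwells (microsecond photoblinking).
#' @param dt simulation time step in seconds.
#' @param sync_rate_hz,n_tcspc_bins,windows instrument timing, see
#'   [photon_stream()] and [gate_windows()].
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(psf = c(0.5, 0.5, 2),
                       D = 40,
                       box = c(2, 2, 8),
                       brightness = 1e5,
                       tau_D0_ns = 3.8,
                       tau_A_ns = 1.7,
                       R0 = 49,
                       corrections = correction_set(
                         background = c(BBpar = 1000, BBperp = 1000,
                                        BRpar = 1000, BRperp = 1000,
                                        RRpar = 1000, RRperp = 1000)),
                       r_D = 0.2, r_A = 0.25,
                       blinking = NULL,
                       dt = 1e-6,
                       sync_rate_hz = 26.67e6,
                       n_tcspc_bins = 4096L,
                       windows = gate_windows()) {
  stopifnot(all(psf > 0), D >= 0, all(box > 0), brightness > 0,
            tau_D0_ns > 0, tau_A_ns > 0, R0 > 0, dt > 0)
  if (!is.null(blinking))
    stopifnot(blinking$k_off > 0, blinking$k_on > 0)
  structure(list(psf = psf, D = D, box = box, brightness = brightness,
                 tau_D0_ns = tau_D0_ns, tau_A_ns = tau_A_ns, R0 = R0,
                 corrections = corrections, r_D = r_D, r_A = r_A,
                 blinking = blinking, dt = dt,
                 sync_rate_hz = sync_rate_hz,
                 n_tcspc_bins = as.integer(n_tcspc_bins),
                 windows = windows),
            class = "sim_config")
}

# Gaussian spot excitation weight at positions (um)
psf_weight <- function(x, y, z, psf) {
  exp(-2 * (x / psf[1])^2 - 2 * (y / psf[2])^2 - 2 * (z / psf[3])^2)
}

# reflect coordinates into [-half, half] (exact folding of Brownian steps)
reflect_coord <- function(x, half) {
  y <- (x + half) %% (4 * half)
  abs(y - 2 * half) - half
}

#' Simulate a Brownian transit trajectory of PSF excitation weights
#'
#' Propagates one molecule through the simulation box with reflecting
#' boundaries and returns the 3D-Gaussian excitation weight sampled on the
#' fixed time grid.
#'
#' @param config a [sim_config()].
#' @param duration trajectory duration in seconds.
#' @param seed optional integer seed.
#' @param x0 optional starting position (um, length 3); default uniform in the
#'   box.
#' @return list with `dt`, `w` (weights per step), and `x_end` (final
#'   position).
#' @export
simulate_diffusion <- function(config, duration, seed = NULL, x0 = NULL) {
  stopifnot(inherits(config, "sim_config"), duration > 0)
  if (any(config$box <= 0)) stop("zero-volume box")
  if (!is.null(seed)) set.seed(seed)
  m <- max(1L, round(duration / config$dt))
  if (is.null(x0)) x0 <- stats::runif(3, -config$box, config$box)
  if (config$D == 0) {
    w <- rep(psf_weight(x0[1], x0[2], x0[3], config$psf), m)
    return(list(dt = config$dt, w = w, x_end = x0))
  }
  sd_step <- sqrt(2 * config$D * config$dt)
  x <- reflect_coord(x0[1] + cumsum(stats::rnorm(m, 0, sd_step)), config$box[1])
  y <- reflect_coord(x0[2] + cumsum(stats::rnorm(m, 0, sd_step)), config$box[2])
  z <- reflect_coord(x0[3] + cumsum(stats::rnorm(m, 0, sd_step)), config$box[3])
  list(dt = config$dt, w = psf_weight(x, y, z, config$psf),
       x_end = c(x[m], y[m], z[m]))
}

# truncated exponential on [0, W)
rtexp <- function(n, tau, W) {
  -tau * log(1 - stats::runif(n) * (1 - exp(-W / tau)))
}

# parallel-polarization probability reproducing steady-state anisotropy r
# under G-factor G:  F_par/F_perp = (1 + 2 r) / (G (1 - r))
p_parallel <- function(r, G) {
  x <- (1 + 2 * r) / (G * (1 - r))
  x / (1 + x)
}

#' Emit photons along excitation-weight trajectories
#'
#' The per-step fluorescence intensity is `brightness * w(t)`. Donor
#' excitations draw a per-photon apparent distance from the current state's
#' Gaussian (fast-linker limit) and branch into donor emission (BB gates, with
#' crosstalk fraction ct re-routed to the BR gates), FRET-sensitized acceptor
#' emission (BR gates, detection factor gamma), or loss. Acceptor-excitation
#' photons appear in the RR gates at rate `gamma*beta*brightness*w`, and
#' direct excitation adds `de` times that rate to the BR gates. Microtimes are
#' single-exponential with the donor lifetime quenched as
#' `tau_D(E) = tau_D0 * (1 - E)` (FRET photons add the acceptor decay),
#' truncated to the PIE windows; polarization is a per-photon Bernoulli draw
#' from the steady-state anisotropy; per-gate Poisson background is added.
#'
#' @param trajectories list of trajectories as returned by
#'   [simulate_diffusion()] (all sharing `dt`); one per molecule, interpreted
#'   as concurrent in the same acquisition.
#' @param state_paths list of state paths from [simulate_state_trajectory()],
#'   aligned with `trajectories`.
#' @param schemes a single [kinetic_scheme()] or a list, one per molecule.
#' @param config a [sim_config()].
#' @param seed optional integer seed.
#' @return a [photon_stream()] with gates assigned.
#' @export
emit_photons <- function(trajectories, state_paths, schemes, config, seed = NULL) {
  stopifnot(length(trajectories) == length(state_paths))
  if (!is.null(seed)) set.seed(seed)
  if (inherits(schemes, "kinetic_scheme"))
    schemes <- rep(list(schemes), length(trajectories))
  dur <- max(vapply(trajectories, function(tr) length(tr$w) * tr$dt, 0))
  parts <- vector("list", length(trajectories))
  for (i in seq_along(trajectories)) {
    tr <- trajectories[[i]]
    if (abs(length(tr$w) * tr$dt - state_paths[[i]]$duration) > tr$dt)
      stop("trajectory and state path lengths are inconsistent")
    parts[[i]] <- emit_photons_one(tr$w, tr$dt, 0, state_paths[[i]],
                                   schemes[[i]], config)
  }
  bg <- emit_background(dur, config)
  assemble_stream(c(parts, list(bg)), dur, config)
}

# emission for one molecule; returns list(t_abs, nanotime, detector)
emit_photons_one <- function(w, dt, t0, path, scheme, config, blink_path = NULL) {
  cr <- config$corrections
  m <- length(w)
  if (!is.null(blink_path)) {
    grid_t <- t0 + (seq_len(m) - 0.5) * dt
    on <- state_at(blink_path, grid_t - t0) == 1L
    w <- w * on
  }
  gamma <- cr$gamma; ct <- cr$ct; de <- cr$de; beta <- cr$beta
  Q <- config$brightness
  c_max <- max(1 + ct, gamma)
  ## one Poisson draw per active step covers all candidate streams; steps
  ## with excitation below ~3e-5 of the peak contribute < 10 photons/s and
  ## are skipped
  c_rr <- gamma * beta
  c_de <- de * c_rr
  c_tot <- c_max + c_rr + c_de
  active <- which(w > 3e-5)
  n_all <- stats::rpois(length(active), Q * w[active] * dt * c_tot)
  idx_all <- rep.int(active, n_all)
  stream_u <- stats::runif(length(idx_all)) * c_tot
  idx <- idx_all[stream_u < c_max]
  out_t <- list(); out_nano <- list(); out_det <- list()
  W_D <- config$windows$donor[2] - config$windows$donor[1]
  W_A <- config$windows$acceptor[2] - config$windows$acceptor[1]
  res <- 1 / (config$sync_rate_hz * config$n_tcspc_bins)
  tau_D0 <- config$tau_D0_ns * 1e-9
  tau_A <- config$tau_A_ns * 1e-9
  if (length(idx)) {
    t_cand <- t0 + (idx - stats::runif(length(idx))) * dt
    st <- state_at(path, t_cand - t0)
    Rm <- scheme$states$R_mean[st]
    Rs <- scheme$states$R_sigma[st]
    R <- ifelse(Rs > 0, stats::rnorm(length(idx), Rm, Rs), Rm)
    R <- pmax(R, 1e-3)
    E <- fret_efficiency_from_distance(R, config$R0)
    u <- stats::runif(length(idx)) * c_max
    type <- integer(length(idx))           # 0 lost, 1 BB, 2 BR-crosstalk, 3 BR-FRET
    p1 <- (1 - E); p2 <- p1 + ct * (1 - E); p3 <- p2 + gamma * E
    type[u < p3] <- 3L
    type[u < p2] <- 2L
    type[u < p1] <- 1L
    keep <- type > 0L
    if (any(keep)) {
      tk <- t_cand[keep]; Ek <- E[keep]; ty <- type[keep]
      tauDk <- pmax(tau_D0 * (1 - Ek), 1e-12)
      delay <- numeric(length(tk))
      don <- ty != 3L
      if (any(don)) delay[don] <- rtexp(sum(don), tauDk[don], W_D)
      if (any(!don)) {
        ii <- which(!don)
        d <- stats::rexp(length(ii), 1 / tauDk[ii]) + stats::rexp(length(ii), 1 / tau_A)
        bad <- which(d >= W_D)
        while (length(bad)) {
          d[bad] <- stats::rexp(length(bad), 1 / tauDk[ii[bad]]) +
            stats::rexp(length(bad), 1 / tau_A)
          bad <- bad[d[bad] >= W_D]
        }
        delay[ii] <- d
      }
      nano <- pmin(as.integer((config$windows$donor[1] + delay) / res),
                   config$n_tcspc_bins - 1L)
      ## polarization: BB uses (r_D, G_B); BR crosstalk is donor emission on the
      ## red detector pair (r_D, G_R); BR FRET is acceptor emission (r_A, G_R)
      ppar <- numeric(length(tk))
      ppar[ty == 1L] <- p_parallel(config$r_D, cr$G_B)
      ppar[ty == 2L] <- p_parallel(config$r_D, cr$G_R)
      ppar[ty == 3L] <- p_parallel(config$r_A, cr$G_R)
      par <- stats::runif(length(tk)) < ppar
      det <- integer(length(tk))
      det[ty == 1L] <- ifelse(par[ty == 1L], 1L, 2L)
      det[ty != 1L] <- ifelse(par[ty != 1L], 3L, 4L)
      out_t[[length(out_t) + 1L]] <- tk
      out_nano[[length(out_nano) + 1L]] <- nano
      out_det[[length(out_det) + 1L]] <- det
    }
  }
  ## acceptor-excitation (RR) and direct-excitation (BR) photons
  for (kind in c("rr", "de")) {
    id2 <- if (kind == "rr") idx_all[stream_u >= c_max & stream_u < c_max + c_rr]
           else idx_all[stream_u >= c_max + c_rr]
    if (!length(id2)) next
    tph <- t0 + (id2 - stats::runif(length(id2))) * dt
    if (kind == "rr") {
      delay <- rtexp(length(id2), tau_A, W_A)
      ## first TCSPC bin lying fully inside the acceptor window
      base_A <- as.integer(ceiling(config$windows$acceptor[1] / res - 1e-9))
      nano <- base_A + as.integer(delay / res)
    } else {
      delay <- rtexp(length(id2), tau_A, W_D)
      nano <- as.integer((config$windows$donor[1] + delay) / res)
    }
    nano <- pmin(nano, config$n_tcspc_bins - 1L)
    par <- stats::runif(length(id2)) < p_parallel(config$r_A, cr$G_R)
    det <- ifelse(par, 3L, 4L)
    out_t[[length(out_t) + 1L]] <- tph
    out_nano[[length(out_nano) + 1L]] <- nano
    out_det[[length(out_det) + 1L]] <- det
  }
  list(t_abs = unlist(out_t), nanotime = unlist(out_nano),
       detector = unlist(out_det))
}

# Poisson background over all six gates, uniform in time and within gate window
emit_background <- function(duration, config) {
  cr <- config$corrections
  res <- 1 / (config$sync_rate_hz * config$n_tcspc_bins)
  gates <- names(cr$background)
  t_all <- list(); nano_all <- list(); det_all <- list()
  det_map <- c(BBpar = 1L, BBperp = 2L, BRpar = 3L, BRperp = 4L,
               RRpar = 3L, RRperp = 4L)
  for (g in gates) {
    rate <- cr$background[[g]]
    if (rate <= 0) next
    n <- stats::rpois(1, rate * duration)
    if (n == 0) next
    win <- if (startsWith(g, "RR")) config$windows$acceptor else config$windows$donor
    t_all[[g]] <- stats::runif(n, 0, duration)
    nano_all[[g]] <- pmin(as.integer(stats::runif(n, win[1], win[2]) / res),
                          config$n_tcspc_bins - 1L)
    det_all[[g]] <- rep.int(det_map[[g]], n)
  }
  list(t_abs = unlist(t_all, use.names = FALSE),
       nanotime = unlist(nano_all, use.names = FALSE),
       detector = unlist(det_all, use.names = FALSE))
}

# merge photon parts, sort, build the stream
assemble_stream <- function(parts, duration, config) {
  t_abs <- unlist(lapply(parts, `[[`, "t_abs"), use.names = FALSE)
  nano <- unlist(lapply(parts, `[[`, "nanotime"), use.names = FALSE)
  det <- unlist(lapply(parts, `[[`, "detector"), use.names = FALSE)
  if (is.null(t_abs)) t_abs <- numeric(0)
  macro <- floor(t_abs * config$sync_rate_hz)
  o <- order(macro, method = "radix")
  photon_stream(macrotime = macro[o],
                nanotime = if (length(o)) nano[o] else integer(0),
                detector = DETECTORS[if (length(o)) det[o] else integer(0)],
                sync_rate_hz = config$sync_rate_hz,
                n_tcspc_bins = config$n_tcspc_bins,
                duration_s = duration,
                windows = config$windows)
}

#' Simulate a full MFD-PIE acquisition
#'
#' Runs `n_molecules` independent molecules concurrently for `duration`
#' seconds each (one molecule per reflecting box; merging independent boxes is
#' equivalent to one larger volume at the same concentration) and merges their
#' photons with the per-gate background. Molecules are assigned kinetic
#' schemes from `schemes` in proportions `scheme_probs` (stratified
#' largest-remainder allocation, so the realised composition tracks the
#' nominal one even for a handful of molecules) -- this is how a statically
#' heterogeneous population (e.g. a non-exchanging low-FRET fraction beside
#' an exchanging pair) is expressed.
#'
#' @param config a [sim_config()].
#' @param schemes a [kinetic_scheme()] or list of them.
#' @param duration acquisition duration in seconds.
#' @param n_molecules number of concurrent molecules.
#' @param scheme_probs molecule-type probabilities (recycled to `schemes`).
#' @param seed integer seed; all randomness flows from it.
#' @return a [photon_stream()].
#' @export
simulate_mfd <- function(config, schemes, duration, n_molecules = 8,
                         scheme_probs = NULL, seed = NULL) {
  stopifnot(inherits(config, "sim_config"), duration > 0)
  if (!is.null(seed)) set.seed(seed)
  if (inherits(schemes, "kinetic_scheme")) schemes <- list(schemes)
  if (is.null(scheme_probs)) scheme_probs <- rep(1 / length(schemes), length(schemes))
  stopifnot(length(scheme_probs) == length(schemes))
  chunk_steps <- 2^21
  parts <- list()
  ## stratified scheme allocation (largest-remainder): keeps the molecule-type
  ## composition close to scheme_probs even for a handful of molecules
  base <- floor(n_molecules * scheme_probs)
  rem <- n_molecules - sum(base)
  if (rem > 0) {
    frac <- n_molecules * scheme_probs - base
    extra <- sample.int(length(schemes), rem, prob = pmax(frac, 1e-12),
                        replace = FALSE)
    base[extra] <- base[extra] + 1L
  }
  mol_scheme <- sample(rep.int(seq_along(schemes), base))
  ## two-level propagation: a coarse Brownian path locates the rare passages
  ## near the focus; only those segments are refined to the fine time grid
  ## (Brownian bridge) and emit photons. Outside the refined zone the
  ## excitation weight is below ~1e-4, i.e. photostream-irrelevant.
  coarse_fac <- 64L
  dt_c <- config$dt * coarse_fac
  sd_c <- sqrt(2 * config$D * dt_c)
  sd_f <- sqrt(2 * config$D * config$dt)
  margin <- 4 * sd_c
  near <- c(config$psf[1] * 2.15 + margin,
            config$psf[2] * 2.15 + margin,
            config$psf[3] * 2.15 + margin)
  for (mol in seq_len(n_molecules)) {
    sc <- schemes[[mol_scheme[mol]]]
    path <- simulate_state_trajectory(sc, duration)
    blink <- NULL
    if (!is.null(config$blinking)) {
      bl_scheme <- kinetic_scheme(data.frame(label = c("on", "off"), E = c(0, 0)),
                                  rates = matrix(c(0, config$blinking$k_off,
                                                   config$blinking$k_on, 0),
                                                 2, 2, byrow = TRUE))
      blink <- simulate_state_trajectory(bl_scheme, duration)
    }
    x <- stats::runif(3, -config$box, config$box)
    if (config$D == 0) {
      m <- round(duration / config$dt)
      w <- rep(psf_weight(x[1], x[2], x[3], config$psf), m)
      parts[[length(parts) + 1L]] <-
        emit_photons_one(w, config$dt, 0, path, sc, config, blink)
      next
    }
    n_c <- ceiling(duration / dt_c)
    chunk_c <- 2^22
    done_c <- 0L
    while (done_c < n_c) {
      m_c <- min(chunk_c, n_c - done_c)
      xs <- reflect_coord(x[1] + cumsum(stats::rnorm(m_c, 0, sd_c)), config$box[1])
      ys <- reflect_coord(x[2] + cumsum(stats::rnorm(m_c, 0, sd_c)), config$box[2])
      zs <- reflect_coord(x[3] + cumsum(stats::rnorm(m_c, 0, sd_c)), config$box[3])
      x0s <- c(x[1], xs[-m_c]); y0s <- c(x[2], ys[-m_c]); z0s <- c(x[3], zs[-m_c])
      near_iv <- (abs(xs) < near[1] & abs(ys) < near[2] & abs(zs) < near[3]) |
        (abs(x0s) < near[1] & abs(y0s) < near[2] & abs(z0s) < near[3])
      if (any(near_iv)) {
        r <- rle(near_iv)
        ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
        for (k in which(r$values)) {
          i1 <- starts[k]; i2 <- ends[k]
          ## refine in slices to bound memory
          s1 <- i1
          while (s1 <= i2) {
            s2 <- min(s1 + 8191L, i2)
            niv <- s2 - s1 + 1L
            iv <- rep.int(seq_len(niv), rep.int(coarse_fac, niv))
            frac <- rep.int(seq_len(coarse_fac), niv) / coarse_fac
            fine <- function(p0, pv, half) {
              ## per-interval Brownian bridges on the fine grid (one global
              ## cumulative walk re-anchored at every coarse endpoint)
              W <- cumsum(stats::rnorm(niv * coarse_fac, 0, sd_f))
              x1 <- pv[s1:s2]
              x0 <- if (niv == 1L) p0 else c(p0, pv[s1:(s2 - 1L)])
              Wend <- W[seq_len(niv) * coarse_fac]
              W0 <- c(0, Wend[-niv])
              pos <- x0[iv] + (W - W0[iv]) +
                frac * (x1[iv] - x0[iv] - (Wend - W0)[iv])
              reflect_coord(pos, half)
            }
            p0x <- if (s1 == 1L) x[1] else xs[s1 - 1L]
            p0y <- if (s1 == 1L) x[2] else ys[s1 - 1L]
            p0z <- if (s1 == 1L) x[3] else zs[s1 - 1L]
            fx <- fine(p0x, xs, config$box[1])
            fy <- fine(p0y, ys, config$box[2])
            fz <- fine(p0z, zs, config$box[3])
            w <- psf_weight(fx, fy, fz, config$psf)
            t0 <- (done_c + s1 - 1L) * dt_c
            len <- niv * coarse_fac * config$dt
            sub_path <- shift_path(path, t0, len)
            sub_blink <- if (is.null(blink)) NULL else shift_path(blink, t0, len)
            parts[[length(parts) + 1L]] <-
              emit_photons_one(w, config$dt, t0, sub_path, sc, config, sub_blink)
            s1 <- s2 + 1L
          }
        }
      }
      x <- c(xs[m_c], ys[m_c], zs[m_c])
      done_c <- done_c + m_c
    }
  }
  parts[[length(parts) + 1L]] <- emit_background(duration, config)
  assemble_stream(parts, duration, config)
}

# restrict a state path to [t0, t0+len) and re-origin it at 0
shift_path <- function(path, t0, len) {
  i0 <- max(findInterval(t0, path$t), 1L)
  i1 <- findInterval(t0 + len, path$t)
  keep <- if (i1 > i0) (i0 + 1L):i1 else integer(0)
  keep <- keep[path$t[keep] > t0]
  list(t = c(0, path$t[keep] - t0),
       state = c(path$state[i0], path$state[keep]),
       duration = len)
}
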