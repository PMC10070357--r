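#' Cut bursts into fixed-duration bins for photon distribution analysis
#'
#' Each burst's photon sequence is cut into consecutive bins of fixed
#' duration (trailing remainders are dropped). Per bin the donor-excitation
#' photon counts (`N` total, `N_R` in the acceptor gates), the corrected
#' FRET efficiency and the uncorrected stoichiometry `S_PR` are recorded.
#' Bins with fewer than `min_photons` or more than `max_photons`
#' donor-excitation photons, or with `S_PR` outside `spr_range`, are removed.
#' The direct-excitation term of the corrected E uses the dataset-average
#' red-excitation count per bin, making the counts-to-E mapping a
#' deterministic function of `(N, N_R)` -- the same mapping the PDA forward
#' model uses.
#'
#' @param ps a [photon_stream()].
#' @param bt burst table (typically the double-labeled selection).
#' @param corrections a [correction_set()].
#' @param durations bin durations in seconds.
#' @param min_photons,max_photons inclusive donor-excitation photon filter.
#' @param spr_range inclusive uncorrected-stoichiometry filter.
#' @param n_grid,E_range FRET-efficiency histogram grid.
#' @return An object of class `pda_data`: per duration a data.frame of bins
#'   (`N`, `N_R`, `E`, `S_PR`) and the E histogram, plus the grid and the
#'   quantities needed by the forward model.
#' @export
bin_bursts <- function(ps, bt, corrections = correction_set(),
                       durations = c(0.5e-3, 1e-3, 2e-3),
                       min_photons = 20, max_photons = 300,
                       spr_range = c(0.2, 0.6),
                       n_grid = 60, E_range = c(-0.1, 1.1)) {
  stopifnot(nrow(bt) > 0)
  ts <- macrotime_s(ps)
  edges <- seq(E_range[1], E_range[2], length.out = n_grid + 1)
  bg <- corrections$background
  out <- vector("list", length(durations))
  for (d in seq_along(durations)) {
    T <- durations[d]
    NG <- NR <- NRR <- integer(0)
    arrivals <- list()
    for (b in seq_len(nrow(bt))) {
      k <- floor(bt$duration_s[b] / T)
      if (k < 1) next
      idx <- bt$i_start[b]:bt$i_end[b]
      rel <- ts[idx] - bt$t_start_s[b]
      bin <- floor(rel / T) + 1L
      ok <- bin <= k
      g <- ps$gate[idx[ok]]; bb <- bin[ok]
      NG <- c(NG, tabulate_gate(bb, g %in% c(1L, 2L), k))
      NR <- c(NR, tabulate_gate(bb, g %in% c(3L, 4L), k))
      NRR <- c(NRR, tabulate_gate(bb, g %in% c(5L, 6L), k))
      arrivals <- c(arrivals,
                    split(rel - (bin - 1) * T, factor(bin, levels = seq_len(k))))
    }
    N <- NG + NR
    keep <- N >= min_photons & N <= max_photons
    ## uncorrected stoichiometry filter (background-corrected counts)
    F_dex <- N - (bg[["BBpar"]] + bg[["BBperp"]] + bg[["BRpar"]] + bg[["BRperp"]]) * T
    F_rr <- NRR - (bg[["RRpar"]] + bg[["RRperp"]]) * T
    S_PR <- ifelse(F_dex + F_rr > 0, F_dex / (F_dex + F_rr), NA_real_)
    keep <- keep & !is.na(S_PR) & S_PR >= spr_range[1] & S_PR <= spr_range[2]
    rr_bar <- if (any(keep)) mean(F_rr[keep]) else 0
    E <- pda_E_from_counts(NG[keep], NR[keep], T, corrections, rr_bar)
    bins <- data.frame(N = N[keep], N_R = NR[keep], E = E, S_PR = S_PR[keep])
    h <- bin_histogram(E, edges)
    out[[d]] <- list(duration = T, bins = bins, hist = h, rr_bar = rr_bar,
                     arrivals = arrivals[keep])
  }
  structure(list(sets = out, edges = edges, corrections = corrections),
            class = "pda_data")
}

tabulate_gate <- function(bin, sel, k) tabulate(bin[sel], nbins = k)

# cached Gauss-Legendre nodes on (0, 1); rescaled by callers
.gl_cache <- new.env(parent = emptyenv())
gl_unit <- function(n) {
  key <- as.character(n)
  if (is.null(.gl_cache[[key]]))
    .gl_cache[[key]] <- pracma::gaussLegendre(n, 0, 1)
  .gl_cache[[key]]
}

bin_histogram <- function(E, edges) {
  n <- length(edges) - 1
  idx <- findInterval(E, edges, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), n)
  tabulate(idx, n)
}

# deterministic counts -> corrected E mapping shared by data and model
pda_E_from_counts <- function(N_G, N_R, T, corrections, rr_bar) {
  cr <- corrections
  bg <- cr$background
  F_G <- N_G - (bg[["BBpar"]] + bg[["BBperp"]]) * T
  F_R <- N_R - (bg[["BRpar"]] + bg[["BRperp"]]) * T
  num <- F_R - cr$ct * F_G - cr$de * rr_bar
  den <- cr$gamma * F_G + num
  ifelse(den != 0, num / den, NA_real_)
}

# acceptor-photon probability among donor-excitation fluorescence photons
# for a molecule with true FRET efficiency E
pda_acceptor_prob <- function(E, corrections) {
  cr <- corrections
  num <- cr$gamma * E + cr$ct * (1 - E) + cr$de * cr$gamma * cr$beta
  den <- (1 - E) * (1 + cr$ct) + cr$gamma * E + cr$de * cr$gamma * cr$beta
  num / den
}

# relative donor-excitation detection rate of a state: with gamma != 1 the
# detected Dex photon rate depends on E, so photons over-sample the state
# with the larger rate
pda_dex_rate <- function(E, corrections) {
  cr <- corrections
  (1 - E) * (1 + cr$ct) + cr$gamma * E + cr$de * cr$gamma * cr$beta
}

#' Occupancy-time distribution of a two-state Markov chain
#'
#' Distribution of the cumulative time `T1` spent in state 1 over a window
#' of length `T`, starting from the stationary distribution. It is a mixture
#' of two point masses (no transition: all of `T` in state 1 with
#' probability `p1 exp(-k12 T)`, all in state 2 with `p2 exp(-k21 T)`) and a
#' continuous transition density expressed through modified Bessel
#' functions:
#' \deqn{f(T_1) = e^{-k_{12} T_1 - k_{21} T_2} [ (p_1 k_{12} + p_2 k_{21})
#'   I_0(u) + (p_1 k_{12} \sqrt{k_{21} T_2 / (k_{12} T_1)}\cdot
#'   \frac{k_{12}T_1}{...}) ]}
#' with `u = 2 sqrt(k12 k21 T1 T2)`; see the package vignette for the
#' derivation via Poisson-clock counting on the per-state occupation clocks.
#'
#' @param k12,k21 exchange rates (1/s), both `>= 0`.
#' @param T window length (s).
#' @param n_nodes Gauss-Legendre nodes for the continuous part.
#' @return list with `atoms` (data.frame `t1`, `w`) and `nodes`
#'   (data.frame `t1`, `w` -- quadrature weight times density). The weights
#'   sum to 1 up to quadrature error.
#' @export
occupancy_time_distribution <- function(k12, k21, T, n_nodes = 33) {
  stopifnot(k12 >= 0, k21 >= 0, T > 0)
  if (k12 + k21 == 0) {
    return(list(atoms = data.frame(t1 = c(T, 0), w = c(0.5, 0.5)),
                nodes = data.frame(t1 = numeric(0), w = numeric(0))))
  }
  p1 <- k21 / (k12 + k21)
  p2 <- k12 / (k12 + k21)
  atoms <- data.frame(t1 = c(T, 0),
                      w = c(p1 * exp(-k12 * T), p2 * exp(-k21 * T)))
  if (k12 == 0 || k21 == 0) {
    ## one direction frozen: the continuous part is a single exponential
    glu <- gl_unit(n_nodes)
    gl <- list(x = glu$x * T, w = glu$w * T)
    t1 <- gl$x; t2 <- T - t1
    dens <- if (k12 == 0) p2 * k21 * exp(-k21 * t2) else p1 * k12 * exp(-k12 * t1)
    return(list(atoms = atoms, nodes = data.frame(t1 = t1, w = gl$w * dens)))
  }
  glu <- gl_unit(n_nodes)
  gl <- list(x = glu$x * T, w = glu$w * T)
  t1 <- gl$x; t2 <- T - t1
  u <- 2 * sqrt(k12 * k21 * t1 * t2)
  pref <- exp(u - k12 * t1 - k21 * t2)
  i0 <- besselI(u, 0, expon.scaled = TRUE)
  i1 <- besselI(u, 1, expon.scaled = TRUE)
  dens <- pref * ((p1 * k12 + p2 * k21) * i0 +
                    (p1 * sqrt(k12 * k21 * t1 / t2) +
                       p2 * sqrt(k12 * k21 * t2 / t1)) * i1)
  list(atoms = atoms, nodes = data.frame(t1 = t1, w = gl$w * dens))
}

#' Effective averaging duration of PDA bins under intensity fluctuations
#'
#' Photons sample the conformational trajectory in proportion to the
#' instantaneous detection rate, which varies while the molecule crosses the
#' spot. The exchange averaging inside a bin is therefore governed not by
#' the nominal bin duration but by an effective, shorter window. This
#' function measures the mean pairwise kernel statistic
#' `M = < exp(-|t_i - t_j| / tau) >` over photon pairs of each bin (an
#' unbiased estimate of the intensity-profile overlap at timescale `tau`)
#' and returns the uniform-window duration with the same statistic, by
#' inverting `M_unif(T) = (2 tau / T) (1 - (tau / T) (1 - exp(-T/tau)))`.
#'
#' @param set one per-duration element of a `pda_data` object (with
#'   `arrivals`).
#' @param tau kernel timescale in seconds -- use the exchange time the
#'   dynamic model is evaluated at.
#' @return effective duration in seconds (at most the nominal duration).
#' @export
pda_effective_duration <- function(set, tau) {
  T <- set$duration
  arr <- set$arrivals
  num <- 0; den <- 0
  for (tt in arr) {
    n <- length(tt)
    if (n < 2) next
    M <- sum(exp(-abs(outer(tt, tt, "-")) / tau)) - n
    num <- num + M
    den <- den + n * (n - 1)
  }
  if (den == 0) return(T)
  M_obs <- num / den
  M_unif <- function(Tw) (2 * tau / Tw) * (1 - (tau / Tw) * (1 - exp(-Tw / tau)))
  if (M_obs <= M_unif(T)) return(T)
  if (M_obs >= M_unif(tau * 1e-3)) return(tau * 1e-3)
  stats::uniroot(function(Tw) M_unif(Tw) - M_obs, c(tau * 1e-3, T))$root
}

## ---- precomputed shot-noise tables -----------------------------------------

# For one bin duration: matrix H[e_bin, eps] = sum_N n(N) P(E_bin | N, eps)
# including the Poisson background convolution in both gate groups.
pda_precompute_table <- function(set, corrections, edges,
                                 eps_grid = seq(0, 1, length.out = 101),
                                 tail_mass = 1e-6) {
  bins <- set$bins
  T <- set$duration
  bg <- corrections$background
  lamG <- (bg[["BBpar"]] + bg[["BBperp"]]) * T
  lamR <- (bg[["BRpar"]] + bg[["BRperp"]]) * T
  BG <- if (lamG > 0) stats::qpois(1 - tail_mass, lamG) else 0L
  BR <- if (lamR > 0) stats::qpois(1 - tail_mass, lamR) else 0L
  wG <- stats::dpois(0:BG, lamG); wG <- wG / sum(wG)
  wR <- stats::dpois(0:BR, lamR); wR <- wR / sum(wR)
  tabN <- table(bins$N)
  Nvals <- as.integer(names(tabN))
  nN <- as.numeric(tabN)
  ne <- length(edges) - 1
  H <- matrix(0, ne, length(eps_grid))
  for (iN in seq_along(Nvals)) {
    N <- Nvals[iN]
    binidx <- pmin(pmax(findInterval(
      pda_E_from_counts(N - (0:N), 0:N, T, corrections, set$rr_bar),
      edges, rightmost.closed = TRUE), 1L), ne)
    P <- matrix(0, N + 1, length(eps_grid))
    for (btot in 0:min(BG + BR, N)) {
      nf <- N - btot
      db <- matrix(stats::dbinom(rep(0:nf, length(eps_grid)), nf,
                                 rep(eps_grid, each = nf + 1)),
                   nf + 1, length(eps_grid))
      for (bR in max(0, btot - BG):min(BR, btot)) {
        rows <- (bR + 0:nf) + 1L
        P[rows, ] <- P[rows, ] + (wG[btot - bR + 1] * wR[bR + 1]) * db
      }
    }
    agg <- rowsum(P, binidx)
    rows <- as.integer(rownames(agg))
    H[rows, ] <- H[rows, ] + nN[iN] * agg
  }
  list(H = H, eps_grid = eps_grid, n_bins = sum(nN))
}

# column of the table at arbitrary eps by linear interpolation
pda_table_column <- function(tab, eps) {
  g <- tab$eps_grid
  eps <- min(max(eps, g[1]), g[length(g)])
  i <- findInterval(eps, g)
  if (i >= length(g)) return(tab$H[, length(g)])
  f <- (eps - g[i]) / (g[i + 1] - g[i])
  (1 - f) * tab$H[, i] + f * tab$H[, i + 1]
}

# expected histogram of one static Gaussian-distance state
pda_static_state_hist <- function(tab, R_mean, R_sigma, R0, corrections,
                                  n_nodes = 17) {
  if (R_sigma <= 0) {
    eps <- pda_acceptor_prob(fret_efficiency_from_distance(R_mean, R0), corrections)
    return(pda_table_column(tab, eps))
  }
  glu <- gl_unit(n_nodes)
  gl <- list(x = glu$x * 10 - 5, w = glu$w * 10)
  R <- R_mean + R_sigma * gl$x
  w <- gl$w * stats::dnorm(gl$x) * (R > 0)
  w <- w / sum(w)
  eps <- pda_acceptor_prob(fret_efficiency_from_distance(pmax(R, 1e-6), R0),
                           corrections)
  out <- 0
  for (k in seq_along(eps)) out <- out + w[k] * pda_table_column(tab, eps[k])
  out
}

# expected histogram of a dynamic two-state pair; T is the effective
# averaging duration of the bins. Photon sampling weights the two states by
# their detection rates (pda_dex_rate): the acceptor fraction is the
# rate-weighted mixture, and bins are drawn in proportion to their expected
# photon yield, which tilts the occupancy distribution toward the brighter
# state.
pda_dynamic_pair_hist <- function(tab, T, st1, st2, k12, k21, R0, corrections,
                                  n_nodes = 33) {
  occ <- occupancy_time_distribution(k12, k21, T, n_nodes)
  eps1 <- gaussian_mean_eps(st1, R0, corrections)
  eps2 <- gaussian_mean_eps(st2, R0, corrections)
  b1 <- pda_dex_rate(fret_efficiency_from_distance(st1[1], R0), corrections)
  b2 <- pda_dex_rate(fret_efficiency_from_distance(st2[1], R0), corrections)
  yield <- function(t1) (t1 * b1 + (T - t1) * b2) / T
  w_atom <- occ$atoms$w * yield(occ$atoms$t1)
  w_node <- if (nrow(occ$nodes)) occ$nodes$w * yield(occ$nodes$t1) else numeric(0)
  norm <- sum(w_atom) + sum(w_node)
  w_atom <- w_atom / norm
  w_node <- w_node / norm
  out <- w_atom[1] *
    pda_static_state_hist(tab, st1[1], st1[2], R0, corrections) +
    w_atom[2] *
    pda_static_state_hist(tab, st2[1], st2[2], R0, corrections)
  if (nrow(occ$nodes)) {
    eff <- (occ$nodes$t1 * b1 * eps1 + (T - occ$nodes$t1) * b2 * eps2) /
      (occ$nodes$t1 * b1 + (T - occ$nodes$t1) * b2)
    for (k in seq_len(nrow(occ$nodes)))
      out <- out + w_node[k] * pda_table_column(tab, eff[k])
  }
  out
}

# linker-averaged acceptor probability of a state (R_mean, R_sigma)
gaussian_mean_eps <- function(st, R0, corrections, n_nodes = 17) {
  if (st[2] <= 0)
    return(pda_acceptor_prob(fret_efficiency_from_distance(st[1], R0), corrections))
  glu <- gl_unit(n_nodes)
  gl <- list(x = glu$x * 10 - 5, w = glu$w * 10)
  R <- st[1] + st[2] * gl$x
  w <- gl$w * stats::dnorm(gl$x) * (R > 0)
  w <- w / sum(w)
  sum(w * pda_acceptor_prob(
    fret_efficiency_from_distance(pmax(R, 1e-6), R0), corrections))
}

#' Expected PDA histograms and goodness of fit for a model
#'
#' Forward model: static states are Gaussian distributions of apparent
#' distance; their acceptor-photon probability is mapped through the
#' crosstalk/direct-excitation/gamma forward rates; photon counts are
#' binomial conditioned on each observed bin's photon number, convolved with
#' the Poisson background of both donor-excitation gate groups, and pushed
#' through the same counts-to-E mapping as the data. A dynamic pair
#' additionally integrates over the occupancy-time distribution of the
#' two-state exchange within the bin. The Poissonian reduced chi-square over
#' occupied histogram bins measures agreement.
#'
#' @param pda a `pda_data` object from [bin_bursts()].
#' @param model list with `states` (matrix/data.frame with columns `R_mean`,
#'   `R_sigma`, one row per state), `areas` (per component: static states
#'   first, then the pair if present; sums to 1), optional `pair` (indices
#'   of the two exchanging states), `k12`, `k21`, and `R0`.
#' @param tables optional precomputed shot-noise tables
#'   ([pda_precompute_tables()]); computed on the fly otherwise.
#' @return list with per-duration expected histograms (`expected`, scaled to
#'   bin counts), the pooled `chi2_red`, and per-duration chi2.
#' @export
pda_expected_histogram <- function(pda, model, tables = NULL) {
  if (is.null(tables)) tables <- pda_precompute_tables(pda)
  states <- as.matrix(model$states[, c("R_mean", "R_sigma")])
  pair <- model$pair
  static_idx <- setdiff(seq_len(nrow(states)), pair)
  cr <- pda$corrections
  R0 <- if (is.null(model$R0)) 49 else model$R0
  expected <- list()
  chi2 <- numeric(length(pda$sets))
  npts <- numeric(length(pda$sets))
  for (d in seq_along(pda$sets)) {
    set <- pda$sets[[d]]
    tab <- tables[[d]]
    H <- 0
    ai <- 1
    for (s in static_idx) {
      H <- H + model$areas[ai] *
        pda_static_state_hist(tab, states[s, 1], states[s, 2], R0, cr)
      ai <- ai + 1
    }
    if (!is.null(pair)) {
      T_dyn <- if (!is.null(model$T_eff)) model$T_eff[d] else set$duration
      H <- H + model$areas[ai] *
        pda_dynamic_pair_hist(tab, T_dyn, states[pair[1], ],
                              states[pair[2], ], model$k12, model$k21, R0, cr)
    }
    ## H columns were built as counts (sum over bins); normalize to totals
    H <- H / max(sum(H), 1e-300) * sum(set$hist)
    expected[[d]] <- H
    use <- H > 1e-3
    chi2[d] <- sum((set$hist[use] - H[use])^2 / H[use])
    npts[d] <- sum(use)
  }
  nfree <- length(model$areas) - 1 + 2 * nrow(states) +
    (if (!is.null(pair)) 1 else 0)
  list(expected = expected, chi2 = chi2,
       chi2_red = sum(chi2) / max(sum(npts) - nfree, 1))
}

#' Precompute the conditional shot-noise tables of a `pda_data` object
#' @param pda a `pda_data` object.
#' @param eps_grid acceptor-probability grid for the tables.
#' @return list of per-duration tables; pass to [pda_expected_histogram()]
#'   or [fit_pda()] to avoid recomputation.
#' @export
pda_precompute_tables <- function(pda, eps_grid = seq(0, 1, length.out = 101)) {
  lapply(pda$sets, function(set)
    pda_precompute_table(set, pda$corrections, pda$edges, eps_grid))
}

#' Fit a PDA model across bin durations (and conditions)
#'
#' Minimises the pooled Poissonian chi-square over all bin durations of all
#' conditions with a Nelder-Mead simplex, multi-started from jittered
#' initial values. State distance means and widths are global across
#' conditions; component areas and (for a dynamic pair) the forward/backward
#' rate ratio are per-condition. The pair's exchange relaxation time
#' `tau_ex = 1/(k12+k21)` is fixed per condition (typically to the fFCS
#' exchange time for agonist data and to a value far beyond the bin duration
#' otherwise).
#'
#' @param pda_list a `pda_data` object or named list of them (one per
#'   condition).
#' @param states_init data.frame with `R_mean`, `R_sigma` initial values.
#' @param pair indices of the exchanging pair among the states, or `NULL`
#'   for an all-static model.
#' @param tau_ex_s fixed exchange time(s), recycled over conditions.
#' @param areas_init optional initial component areas.
#' @param fit_sigma fit one shared width (TRUE) or freeze the initial
#'   widths.
#' @param restarts number of jittered simplex restarts.
#' @param maxit simplex iterations per restart.
#' @param seed integer seed for the jitter.
#' @param use_effective_duration evaluate the dynamic pair on the
#'   empirically calibrated effective bin duration
#'   ([pda_effective_duration()]) instead of the nominal one.
#' @param tables optional precomputed [pda_precompute_tables()] per
#'   condition.
#' @return list with `states` (fitted means/widths and state E), per
#'   condition `areas`, `populations` (per state, pair split by the
#'   stationary ratio), `k12`, `k21`, and the global `chi2_red`.
#' @export
fit_pda <- function(pda_list, states_init, pair = NULL, tau_ex_s = 0.2,
                    areas_init = NULL, fit_sigma = TRUE,
                    restarts = 10, maxit = 400, seed = 1,
                    use_effective_duration = TRUE, tables = NULL) {
  if (inherits(pda_list, "pda_data")) pda_list <- list(pda_list)
  ncond <- length(pda_list)
  tau_ex_s <- rep_len(tau_ex_s, ncond)
  if (is.null(tables)) tables <- lapply(pda_list, pda_precompute_tables)
  ## effective averaging window per condition x duration (intensity-weighted
  ## exchange averaging; see pda_effective_duration)
  T_eff <- lapply(seq_len(ncond), function(i) {
    vapply(pda_list[[i]]$sets, function(set) {
      if (use_effective_duration && !is.null(set$arrivals))
        pda_effective_duration(set, tau_ex_s[i])
      else set$duration
    }, 0)
  })
  S <- nrow(states_init)
  static_idx <- setdiff(seq_len(S), pair)
  ncomp <- length(static_idx) + (if (!is.null(pair)) 1 else 0)
  if (is.null(areas_init)) areas_init <- rep(1 / ncomp, ncomp)
  R0 <- 49
  ## theta: log R (S), [log sigma], per condition: (ncomp-1) area logits,
  ## [logit p_hi] if pair
  build_theta <- function() {
    th <- log(states_init$R_mean)
    if (fit_sigma) th <- c(th, log(max(mean(states_init$R_sigma), 1)))
    for (i in seq_len(ncond)) {
      if (ncomp > 1)
        th <- c(th, stats::qlogis(pmin(pmax(
          areas_init[-ncomp] / sum(areas_init), 0.02), 0.98)))
      if (!is.null(pair)) th <- c(th, 0)
    }
    th
  }
  unpack <- function(th) {
    Rm <- exp(th[seq_len(S)])
    pos <- S
    sig <- states_init$R_sigma
    if (fit_sigma) { pos <- pos + 1; sig <- rep(exp(th[pos]), S) }
    conds <- vector("list", ncond)
    for (i in seq_len(ncond)) {
      if (ncomp > 1) {
        raw <- stats::plogis(th[pos + seq_len(ncomp - 1)])
        pos <- pos + ncomp - 1
        ## stick-breaking style normalization
        areas <- c(raw, 1)
        areas <- areas / sum(areas)
      } else areas <- 1
      p_hi <- NA
      if (!is.null(pair)) { pos <- pos + 1; p_hi <- stats::plogis(th[pos]) }
      conds[[i]] <- list(areas = areas, p_hi = p_hi)
    }
    list(R_mean = Rm, R_sigma = sig, conds = conds)
  }
  objective <- function(th) {
    pp <- unpack(th)
    ## keep the state identity fixed: distances strictly decreasing
    if (any(diff(pp$R_mean) >= -1e-9)) return(1e12)
    states <- data.frame(R_mean = pp$R_mean, R_sigma = pp$R_sigma)
    tot <- 0
    for (i in seq_len(ncond)) {
      k_sum <- 1 / tau_ex_s[i]
      model <- list(states = states, areas = pp$conds[[i]]$areas,
                    pair = pair, R0 = R0, T_eff = T_eff[[i]],
                    k12 = if (!is.null(pair)) pp$conds[[i]]$p_hi * k_sum else 0,
                    k21 = if (!is.null(pair)) (1 - pp$conds[[i]]$p_hi) * k_sum else 0)
      res <- pda_expected_histogram(pda_list[[i]], model, tables[[i]])
      tot <- tot + sum(res$chi2)
    }
    if (!is.finite(tot)) tot <- 1e12
    tot
  }
  set.seed(seed)
  th0 <- build_theta()
  best <- NULL
  for (r in seq_len(restarts)) {
    st <- if (r == 1) th0 else th0 + stats::rnorm(length(th0), 0, 0.15)
    opt <- NULL
    ## iterated simplex: restart from the incumbent until it stops improving
    for (round in 1:6) {
      cur <- stats::optim(st, objective, method = "Nelder-Mead",
                          control = list(maxit = maxit, reltol = 1e-7))
      if (!is.null(opt) && opt$value - cur$value < 1e-2) { opt <- cur; break }
      opt <- cur
      st <- cur$par
    }
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  pp <- unpack(best$par)
  states <- data.frame(R_mean = pp$R_mean, R_sigma = pp$R_sigma)
  states$E <- fret_efficiency_from_distance(states$R_mean, R0)
  conds <- vector("list", ncond)
  chi2_red <- 0; npts <- 0
  for (i in seq_len(ncond)) {
    k_sum <- 1 / tau_ex_s[i]
    k12 <- if (!is.null(pair)) pp$conds[[i]]$p_hi * k_sum else 0
    k21 <- if (!is.null(pair)) (1 - pp$conds[[i]]$p_hi) * k_sum else 0
    model <- list(states = states, areas = pp$conds[[i]]$areas, pair = pair,
                  R0 = R0, k12 = k12, k21 = k21, T_eff = T_eff[[i]])
    res <- pda_expected_histogram(pda_list[[i]], model, tables[[i]])
    pops <- numeric(S)
    ai <- 1
    for (s in setdiff(seq_len(S), pair)) { pops[s] <- model$areas[ai]; ai <- ai + 1 }
    if (!is.null(pair)) {
      pops[pair[1]] <- model$areas[ai] * (1 - pp$conds[[i]]$p_hi)
      pops[pair[2]] <- model$areas[ai] * pp$conds[[i]]$p_hi
    }
    conds[[i]] <- list(areas = model$areas, populations = pops,
                       k12 = k12, k21 = k21, chi2 = res$chi2,
                       chi2_red = res$chi2_red, expected = res$expected)
  }
  names(conds) <- names(pda_list)
  list(states = states, conditions = conds,
       chi2_total = best$value, convergence = best$convergence,
       value = best$value)
}
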