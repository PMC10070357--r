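## Draw PDA bins directly from the forward model's own assumptions:
## per-bin quasi-static Gaussian distance for static components, a CTMC
## occupancy path for the dynamic pair, Poisson backgrounds, binomial
## acceptor counts. Returns a `pda_data`-shaped object.
sample_pda_bins <- function(states, areas, pair = NULL, k12 = 0, k21 = 0,
                            n_bins = 5000, T = 1e-3, rate = 5e4,
                            corrections = identity_corrections(),
                            bg_rate = 0, seed = 1,
                            n_grid = 60, E_range = c(-0.1, 1.1)) {
  set.seed(seed)
  if (length(T) > 1) {
    ## multi-duration set: one sub-draw per duration
    sets <- lapply(seq_along(T), function(d) {
      sample_pda_bins(states, areas, pair, k12, k21,
                      n_bins = ceiling(n_bins / length(T)), T = T[d],
                      rate = rate, corrections = corrections,
                      bg_rate = bg_rate, seed = seed + 1000 * d,
                      n_grid = n_grid, E_range = E_range)
    })
    out <- sets[[1]]
    out$sets <- lapply(sets, function(x) x$sets[[1]])
    return(out)
  }
  edges <- seq(E_range[1], E_range[2], length.out = n_grid + 1)
  static_idx <- setdiff(seq_len(nrow(states)), pair)
  comp_labels <- c(static_idx, if (!is.null(pair)) 0L)   # 0 marks the pair
  eps_of <- function(R) mfdburst:::pda_acceptor_prob(
    fret_efficiency_from_distance(pmax(R, 1e-6), 49), corrections)
  pair_scheme <- NULL
  if (!is.null(pair)) {
    pair_scheme <- kinetic_scheme(
      data.frame(label = c("a", "b"), E = c(0.1, 0.9)),
      rates = matrix(c(0, k12, k21, 0), 2, 2, byrow = TRUE))
  }
  N <- N_R <- integer(n_bins)
  for (i in seq_len(n_bins)) {
    comp <- sample(comp_labels, 1, prob = areas)
    ## brightness variability spreads the photon counts over the filter range
    nf <- rpois(1, rate * T * exp(rnorm(1, 0, 0.5)))
    bG <- rpois(1, bg_rate * T); bR <- rpois(1, bg_rate * T)
    if (comp != 0L) {
      R <- rnorm(1, states$R_mean[comp], states$R_sigma[comp])
      eps <- eps_of(R)
    } else {
      p <- simulate_state_trajectory(pair_scheme, T)
      if (length(p$t) == 1) {
        ## no transition: quasi-static distance draw, like a static bin
        s_idx <- pair[p$state[1]]
        eps <- eps_of(rnorm(1, states$R_mean[s_idx], states$R_sigma[s_idx]))
      } else {
        t1 <- sum(diff(c(p$t, T))[p$state == 1])
        e1 <- mfdburst:::gaussian_mean_eps(
          c(states$R_mean[pair[1]], states$R_sigma[pair[1]]), 49, corrections)
        e2 <- mfdburst:::gaussian_mean_eps(
          c(states$R_mean[pair[2]], states$R_sigma[pair[2]]), 49, corrections)
        eps <- (t1 * e1 + (T - t1) * e2) / T
      }
    }
    N[i] <- nf + bG + bR
    N_R[i] <- rbinom(1, nf, eps) + bR
  }
  keep <- N >= 20 & N <= 300
  N <- N[keep]; N_R <- N_R[keep]
  bgv <- c(BBpar = bg_rate / 2, BBperp = bg_rate / 2,
           BRpar = bg_rate / 2, BRperp = bg_rate / 2,
           RRpar = 0, RRperp = 0)
  cr <- correction_set(ct = corrections$ct, de = corrections$de,
                       gamma = corrections$gamma, beta = corrections$beta,
                       G_B = corrections$G_B, G_R = corrections$G_R,
                       background = bgv)
  E <- mfdburst:::pda_E_from_counts(N - N_R, N_R, T, cr, 0)
  structure(list(
    sets = list(list(duration = T,
                     bins = data.frame(N = N, N_R = N_R, E = E, S_PR = 0.45),
                     hist = mfdburst:::bin_histogram(E, edges),
                     rr_bar = 0)),
    edges = edges, corrections = cr), class = "pda_data")
}
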