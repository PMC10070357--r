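#' Time-resolved anisotropy decay from polarized photon delays
#'
#' Histograms the parallel and perpendicular microtimes of one dye's gates
#' (BB for the donor, RR for the acceptor) and computes
#' `r(t) = (G F_par(t) - F_perp(t)) / (G F_par(t) + 2 F_perp(t))` on the
#' microtime grid. The time origin is placed at the peak of the summed
#' decay. The attached weights `G F_par + 2 F_perp` make the count-weighted
#' time average of `r(t)` identical to the steady-state anisotropy of the
#' same photons.
#'
#' @param ps a [photon_stream()].
#' @param idx photon indices to use (e.g. the photons of single-labeled
#'   bursts); default all.
#' @param dye `"donor"` (BB gates, G_B) or `"acceptor"` (RR gates, G_R).
#' @param corrections a [correction_set()] supplying the G factor.
#' @param bin_width_ns histogram bin width in nanoseconds.
#' @return data.frame with `t_ns` (from the decay peak), `r`, `weight`,
#'   `F_par`, `F_perp`.
#' @export
decay_from_photons <- function(ps, idx = seq_len(length(ps)),
                               dye = c("donor", "acceptor"),
                               corrections = correction_set(),
                               bin_width_ns = 0.1) {
  dye <- match.arg(dye)
  gates <- if (dye == "donor") c(1L, 2L) else c(5L, 6L)
  G <- if (dye == "donor") corrections$G_B else corrections$G_R
  g <- ps$gate[idx]
  par_sel <- idx[g == gates[1]]
  perp_sel <- idx[g == gates[2]]
  if (!length(par_sel) || !length(perp_sel))
    stop("no photons in the ", dye, " parallel/perpendicular gates")
  res_ns <- microtime_resolution(ps) * 1e9
  t_par <- ps$nanotime[par_sel] * res_ns
  t_perp <- ps$nanotime[perp_sel] * res_ns
  rng <- range(c(t_par, t_perp))
  edges <- seq(rng[1], rng[2] + bin_width_ns, by = bin_width_ns)
  h_par <- bin_histogram(t_par, edges)
  h_perp <- bin_histogram(t_perp, edges)
  tot <- G * h_par + 2 * h_perp
  peak <- which.max(h_par + h_perp)
  mid <- (edges[-length(edges)] + edges[-1]) / 2
  keep <- tot > 0
  data.frame(t_ns = mid[keep] - mid[peak],
             r = (G * h_par[keep] - h_perp[keep]) / tot[keep],
             weight = tot[keep],
             F_par = h_par[keep], F_perp = h_perp[keep])
}

#' Fit the biexponential anisotropy decay model
#'
#' Weighted least-squares fit of
#' `r(t) = ((r0 - rp) exp(-t/rho_F) + rp) exp(-t/rho_p)`:
#' a fast dye-wobbling decay from the fundamental anisotropy `r0` to the
#' residual anisotropy `rp`, damped by the slow tumbling of the whole
#' particle with rotational correlation time `rho_p` (bounded below, and
#' reported as "greater than the bound" when it runs into the upper search
#' bound -- slow tumbling is barely resolvable within a ns-range gate).
#'
#' @param decay data.frame from [decay_from_photons()] (`t_ns`, `r`,
#'   `weight`); negative-time points are dropped.
#' @param rho_p_bounds_ns lower/upper bounds for the slow time.
#' @param min_points minimum usable grid points.
#' @return list with `r0`, `rp`, `rho_F_ns`, `rho_p_ns`,
#'   `rho_p_at_bound` (TRUE when the slow time hit its upper bound),
#'   `identifiable` (FALSE when the fast time collapses, e.g. for a
#'   constant decay), and the `nls.lm` fit object.
#' @export
fit_anisotropy_decay <- function(decay, rho_p_bounds_ns = c(10, 1e4),
                                 min_points = 20) {
  d <- decay[decay$t_ns >= 0 & is.finite(decay$r) & decay$weight > 0, ]
  if (nrow(d) < min_points)
    stop("need at least ", min_points, " decay points with counts")
  w <- sqrt(d$weight / max(d$weight))
  model <- function(p, t) {
    ((p[1] - p[2]) * exp(-t / p[3]) + p[2]) * exp(-t / p[4])
  }
  resid_fun <- function(p) w * (d$r - model(p, d$t_ns))
  r0_init <- max(min(d$r[which.min(abs(d$t_ns))], 0.39), 0.05)
  rp_init <- max(stats::median(d$r[d$t_ns > stats::quantile(d$t_ns, 0.6)]), 0.01)
  fit <- minpack.lm::nls.lm(
    par = c(r0 = r0_init, rp = min(rp_init, r0_init * 0.9),
            rho_F = 1, rho_p = 60),
    lower = c(-0.2, -0.2, 0.01, rho_p_bounds_ns[1]),
    upper = c(0.5, 0.5, 50, rho_p_bounds_ns[2]),
    fn = resid_fun,
    control = minpack.lm::nls.lm.control(maxiter = 300))
  p <- fit$par
  at_bound <- p[4] > 0.98 * rho_p_bounds_ns[2]
  identifiable <- abs(p[1] - p[2]) > 0.01
  list(r0 = unname(p[1]), rp = unname(p[2]),
       rho_F_ns = unname(p[3]), rho_p_ns = unname(p[4]),
       rho_p_at_bound = at_bound, identifiable = identifiable,
       fit = fit)
}

#' Wobbling-in-a-cone semi-angle from the residual anisotropy
#'
#' Inverts `rp / r0* = (cos(theta) (1 + cos(theta)) / 2)^2` for the cone
#' semi-angle: with `s = sqrt(rp / r0*)`, the positive root of
#' `c^2 + c - 2 s = 0` gives `cos(theta)` and `theta = acos(c)`.
#'
#' @param rp residual anisotropy, `0 <= rp <= r0_star`.
#' @param r0_star reference fundamental anisotropy (0.4 for rigid dyes).
#' @param digits decimals of the returned angle (default one).
#' @return cone semi-angle in degrees.
#' @examples
#' cone_semiangle(0.12)  # ~48.7 degrees
#' @export
cone_semiangle <- function(rp, r0_star = 0.4, digits = 1) {
  if (any(rp < 0) || any(rp > r0_star))
    stop("rp must lie in [0, r0_star]")
  s <- sqrt(rp / r0_star)
  cth <- (-1 + sqrt(1 + 8 * s)) / 2
  round(acos(pmin(cth, 1)) * 180 / pi, digits)
}

#' Simulate polarized photon delays from an anisotropy-decay truth
#'
#' Fixture generator for the time-resolved anisotropy machinery: draws
#' photon delays from a single-exponential intensity decay and assigns
#' polarization with the time-dependent probability implied by the model
#' `r(t) = ((r0 - rp) exp(-t/rho_F) + rp) exp(-t/rho_p)` and the G factor.
#'
#' @param n number of photons.
#' @param tau_ns fluorescence lifetime.
#' @param r0,rp,rho_F_ns,rho_p_ns anisotropy-decay truth.
#' @param G polarization G factor.
#' @param window_ns gate window (delays truncated).
#' @param seed integer seed.
#' @return data.frame with `t_ns` and `parallel` (logical).
#' @export
simulate_polarized_decay <- function(n, tau_ns = 3.8, r0 = 0.37, rp = 0.14,
                                     rho_F_ns = 1, rho_p_ns = 60, G = 1,
                                     window_ns = 18, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- rtexp(n, tau_ns, window_ns)
  r_t <- ((r0 - rp) * exp(-t / rho_F_ns) + rp) * exp(-t / rho_p_ns)
  ppar <- p_parallel(r_t, G)
  data.frame(t_ns = t, parallel = stats::runif(n) < ppar)
}
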