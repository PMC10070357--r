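#' Label bursts as double-labeled, donor-only or acceptor-only
#'
#' Applies the standard MFD-PIE selection windows on the per-burst
#' quantities:
#' * double-labeled: `ALEX-2CDE < 15`, `0.1 < E < 1.0`, `0.2 < S < 0.8`,
#'   `0.1 ns < tau_D < 4.5 ns`, `0.1 ns < tau_A < 8 ns`,
#'   `-0.2 < r_D < 0.6`, `-0.2 < r_A < 0.6`;
#' * donor-only: `ALEX-2CDE > 20`, `-0.1 < E < 0.1`, `0.9 < S < 1.1`,
#'   `0.1 ns < tau_D < 6 ns`, `-0.2 < r_D < 0.6`;
#' * acceptor-only: `ALEX-2CDE > 20`, `0.6 < E < 1.1`, `-0.1 < S < 0.2`,
#'   `0.1 ns < tau_A < 8 ns`, `-0.2 < r_A < 0.6`.
#'
#' All comparisons are strict; a missing quantity fails its window. Bursts
#' matching no class are `unclassified`.
#'
#' @param bt burst table from [analyze_bursts()] (columns `alex_2cde`, `E`,
#'   `S`, `tau_D_ns`, `tau_A_ns`, `r_D`, `r_A`).
#' @return character vector with one of `double`, `donor_only`,
#'   `acceptor_only`, `unclassified` per burst.
#' @export
select_species <- function(bt) {
  w <- function(x, lo, hi) !is.na(x) & x > lo & x < hi
  dbl <- w(bt$alex_2cde, -Inf, 15) & w(bt$E, 0.1, 1.0) & w(bt$S, 0.2, 0.8) &
    w(bt$tau_D_ns, 0.1, 4.5) & w(bt$tau_A_ns, 0.1, 8) &
    w(bt$r_D, -0.2, 0.6) & w(bt$r_A, -0.2, 0.6)
  don <- w(bt$alex_2cde, 20, Inf) & w(bt$E, -0.1, 0.1) & w(bt$S, 0.9, 1.1) &
    w(bt$tau_D_ns, 0.1, 6) & w(bt$r_D, -0.2, 0.6)
  acc <- w(bt$alex_2cde, 20, Inf) & w(bt$E, 0.6, 1.1) & w(bt$S, -0.1, 0.2) &
    w(bt$tau_A_ns, 0.1, 8) & w(bt$r_A, -0.2, 0.6)
  out <- rep("unclassified", nrow(bt))
  out[acc] <- "acceptor_only"
  out[don] <- "donor_only"
  out[dbl] <- "double"
  out
}

#' Fit the gamma and beta detection factors from double-labeled bursts
#'
#' After crosstalk and direct-excitation correction, the inverse
#' stoichiometry of double-labeled molecules is linear in the FRET
#' efficiency: `1/S = Omega + Sigma * E`, with `Omega = 1 + gamma*beta` and
#' `Sigma = beta * (1 - gamma)`. A straight-line fit of `1/S` vs `E` on
#' bursts preselected by `ALEX-2CDE < 15`, `0.1 < E < 1`, `0.2 < S < 0.6`
#' yields
#' \deqn{\gamma = (\Omega - 1) / (\Omega + \Sigma - 1), \quad
#'       \beta = \Omega + \Sigma - 1}
#'
#' @param bt burst table with gate counts and durations ([analyze_bursts()]
#'   output, or anything carrying `S_BB`/`BBpar`... columns plus
#'   `duration_s` and `alex_2cde`).
#' @param corrections a [correction_set()] providing ct, de and background
#'   rates; its gamma/beta are ignored (set to 1 for the preselection
#'   quantities).
#' @param min_bursts calibration error below this number of selected bursts.
#' @param axis `"inv_S_on_E"` (default) regresses 1/S on E;
#'   `"E_on_inv_S"` regresses E on 1/S and inverts the line.
#' @return list with `Omega`, `Sigma`, `gamma`, `beta`, `n_bursts`, and the
#'   underlying `fit` (an `lm`).
#' @export
fit_correction_factors <- function(bt, corrections = correction_set(),
                                   min_bursts = 100,
                                   axis = c("inv_S_on_E", "E_on_inv_S")) {
  axis <- match.arg(axis)
  pre <- correction_set(ct = corrections$ct, de = corrections$de,
                        gamma = 1, beta = 1,
                        G_B = corrections$G_B, G_R = corrections$G_R,
                        background = corrections$background)
  q <- compute_burst_quantities(bt, bt$duration_s, pre)
  sel <- !is.na(q$E) & !is.na(q$S) & q$E > 0.1 & q$E < 1 &
    q$S > 0.2 & q$S < 0.6
  if (!is.null(bt$alex_2cde)) sel <- sel & bt$alex_2cde < 15
  n <- sum(sel)
  if (n < min_bursts)
    stop("calibration error: only ", n, " bursts after preselection")
  E <- q$E[sel]; invS <- 1 / q$S[sel]
  if (stats::sd(E) < 0.12)
    stop("calibration error: degenerate design (E spread is shot-noise level; ",
         "need bursts covering a range of FRET efficiencies)")
  if (axis == "inv_S_on_E") {
    fit <- stats::lm(invS ~ E)
    Omega <- unname(stats::coef(fit)[1])
    Sigma <- unname(stats::coef(fit)[2])
  } else {
    fit <- stats::lm(E ~ invS)
    a <- unname(stats::coef(fit)[1]); b <- unname(stats::coef(fit)[2])
    Sigma <- 1 / b
    Omega <- -a / b
  }
  beta <- Omega + Sigma - 1
  gamma <- (Omega - 1) / beta
  list(Omega = Omega, Sigma = Sigma, gamma = gamma, beta = beta,
       n_bursts = n, fit = fit)
}
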