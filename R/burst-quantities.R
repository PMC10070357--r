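#' Estimate per-gate background rates
#'
#' From a blank (buffer) measurement the rate is simply count/duration per
#' gate. From a sample stream, burst regions are excised first: photons
#' inside bursts and the summed burst duration are removed before dividing.
#'
#' @param ps a [photon_stream()] with gates assigned.
#' @param bursts optional burst table from [find_bursts()]; when supplied,
#'   burst photons and burst time are excised.
#' @return named numeric vector of rates (Hz) over the six live gates.
#' @export
estimate_background <- function(ps, bursts = NULL) {
  stopifnot(inherits(ps, "photon_stream"))
  if (ps$duration_s <= 0) stop("stream duration must be positive")
  counts <- gate_counts(ps)[1:6]
  time <- ps$duration_s
  if (!is.null(bursts) && nrow(bursts)) {
    in_burst <- unlist(mapply(seq, bursts$i_start, bursts$i_end, SIMPLIFY = FALSE))
    counts <- counts - gate_counts(ps, in_burst)[1:6]
    time <- time - sum(bursts$duration_s)
    if (time <= 0) stop("bursts cover the whole stream; no background region left")
  }
  counts / time
}

# gate-group photon counts (summed over polarization) and polarized counts
burst_gate_counts <- function(ps, bursts) {
  n <- nrow(bursts)
  out <- matrix(0L, n, 6, dimnames = list(NULL, GATES[1:6]))
  for (b in seq_len(n)) {
    idx <- bursts$i_start[b]:bursts$i_end[b]
    out[b, ] <- tabulate(ps$gate[idx], nbins = 7L)[1:6]
  }
  as.data.frame(out)
}

#' Corrected FRET efficiency, stoichiometry and proximity ratios per burst
#'
#' Applies the standard MFD-PIE corrections to background-corrected gate
#' counts. With `F_X = S_X - B_X` (X in BB, BR, RR; counts summed over
#' polarization):
#' \deqn{E = (F_BR - ct F_BB - de F_RR) / (\gamma F_BB + F_BR - ct F_BB - de F_RR)}
#' \deqn{S = (\gamma F_BB + F_BR - ct F_BB - de F_RR) /
#'           (\gamma F_BB + F_BR - ct F_BB - de F_RR + F_RR / \beta)}
#' The proximity ratio `PR` and the uncorrected stoichiometry `S_PR` are the
#' same quantities with all of ct, de, gamma, beta switched off (background
#' correction retained). Zero denominators yield `NA` (the burst is excluded
#' downstream), never an error.
#'
#' @param counts data.frame with per-burst polarized gate counts (columns
#'   `BBpar`...`RRperp`) as produced internally, or summed columns `S_BB`,
#'   `S_BR`, `S_RR`.
#' @param duration_s per-burst durations in seconds (recycled), used to turn
#'   background rates into expected counts.
#' @param corrections a [correction_set()].
#' @return data.frame with `F_BB`, `F_BR`, `F_RR`, `E`, `S`, `PR`, `S_PR`.
#' @export
compute_burst_quantities <- function(counts, duration_s, corrections) {
  cr <- corrections
  if (!is.null(counts$S_BB)) {
    S_BB <- counts$S_BB; S_BR <- counts$S_BR; S_RR <- counts$S_RR
  } else {
    S_BB <- counts$BBpar + counts$BBperp
    S_BR <- counts$BRpar + counts$BRperp
    S_RR <- counts$RRpar + counts$RRperp
  }
  bg <- cr$background
  F_BB <- S_BB - (bg[["BBpar"]] + bg[["BBperp"]]) * duration_s
  F_BR <- S_BR - (bg[["BRpar"]] + bg[["BRperp"]]) * duration_s
  F_RR <- S_RR - (bg[["RRpar"]] + bg[["RRperp"]]) * duration_s
  num <- F_BR - cr$ct * F_BB - cr$de * F_RR
  den_E <- cr$gamma * F_BB + num
  E <- ifelse(den_E != 0, num / den_E, NA_real_)
  den_S <- den_E + F_RR / cr$beta
  S <- ifelse(den_S != 0, den_E / den_S, NA_real_)
  den_PR <- F_BB + F_BR
  PR <- ifelse(den_PR != 0, F_BR / den_PR, NA_real_)
  den_SPR <- den_PR + F_RR
  S_PR <- ifelse(den_SPR != 0, den_PR / den_SPR, NA_real_)
  data.frame(F_BB = F_BB, F_BR = F_BR, F_RR = F_RR,
             E = E, S = S, PR = PR, S_PR = S_PR)
}

#' Burst-wise steady-state fluorescence anisotropy
#'
#' `r = (G F_par - F_perp) / (G F_par + 2 F_perp)` with the polarization
#' G factor of the respective detector pair (`G_B` for the donor from the BB
#' gates, `G_R` for the acceptor from the RR gates).
#'
#' @param F_par,F_perp background-corrected counts in the parallel and
#'   perpendicular gate of one dye.
#' @param G polarization G factor.
#' @return anisotropy values; `NA` where the denominator is zero.
#' @export
burstwise_anisotropy <- function(F_par, F_perp, G) {
  den <- G * F_par + 2 * F_perp
  ifelse(den != 0, (G * F_par - F_perp) / den, NA_real_)
}

#' Full per-burst analysis table
#'
#' Runs the complete per-burst photometry: gate counts, background-corrected
#' fluorescence, corrected E and S, proximity ratios, donor/acceptor
#' lifetimes by maximum likelihood, steady-state anisotropies, and the
#' ALEX-2CDE and FRET-2CDE scores; finally labels each burst by species.
#'
#' @param ps a [photon_stream()] with gates assigned.
#' @param bursts burst table from [find_bursts()]; default runs the search
#'   with its defaults.
#' @param corrections a [correction_set()] (including background rates).
#' @param tau_kernel_s kernel time constant of the 2CDE scores (s).
#' @param lifetimes,cde_scores logical switches for the expensive columns.
#' @return the burst table extended with counts, `F_*`, `E`, `S`, `PR`,
#'   `S_PR`, `tau_D_ns`, `tau_A_ns`, `r_D`, `r_A`, `alex_2cde`, `fret_2cde`
#'   and `species`.
#' @export
analyze_bursts <- function(ps, bursts = find_bursts(ps),
                           corrections = correction_set(),
                           tau_kernel_s = 100e-6,
                           lifetimes = TRUE, cde_scores = TRUE) {
  stopifnot(inherits(ps, "photon_stream"))
  if (!nrow(bursts)) return(cbind(bursts))
  cnt <- burst_gate_counts(ps, bursts)
  q <- compute_burst_quantities(cnt, bursts$duration_s, corrections)
  bt <- cbind(bursts, cnt, q)
  bg <- corrections$background
  ## polarized background-corrected counts for anisotropies
  FBBp <- cnt$BBpar - bg[["BBpar"]] * bursts$duration_s
  FBBs <- cnt$BBperp - bg[["BBperp"]] * bursts$duration_s
  FRRp <- cnt$RRpar - bg[["RRpar"]] * bursts$duration_s
  FRRs <- cnt$RRperp - bg[["RRperp"]] * bursts$duration_s
  bt$r_D <- burstwise_anisotropy(FBBp, FBBs, corrections$G_B)
  bt$r_A <- burstwise_anisotropy(FRRp, FRRs, corrections$G_R)
  if (lifetimes) {
    lt <- burst_lifetimes(ps, bursts, corrections)
    bt$tau_D_ns <- lt$tau_D_ns
    bt$tau_A_ns <- lt$tau_A_ns
  }
  if (cde_scores) {
    pd <- burst_photon_data(ps, bursts)
    bt$alex_2cde <- vapply(pd, function(p)
      alex_2cde(p$t_dex, p$t_aex, tau_kernel_s), 0)
    bt$fret_2cde <- vapply(pd, function(p)
      fret_2cde(p$t_dex, p$acc, tau_kernel_s), 0)
  }
  if (lifetimes && cde_scores) bt$species <- select_species(bt)
  bt
}
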