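# exponential kernel density sums between two sorted photon-time vectors
kde_cross <- function(t_eval, t_src, tau) {
  if (!length(t_eval)) return(numeric(0))
  if (!length(t_src)) return(numeric(length(t_eval)))
  colSums(exp(-abs(outer(t_src, t_eval, "-")) / tau))
}

#' ALEX-2CDE score of one burst
#'
#' Kernel-density estimator of stoichiometry fluctuations within a burst.
#' With `KDE_i^X = sum_{j in X} exp(-|t_i - t_j| / tau)` over the
#' donor-excitation (Dex) and acceptor-excitation (Aex) photon streams, and
#' the neighbour-excluded `nbKDE` for a photon's own stream, the score is
#' `100 - 50 * (BR_Aex + BR_Dex)` where `BR_Aex` averages the Aex/Dex local
#' brightness ratio over Dex photons (normalised by the Aex photon number)
#' and `BR_Dex` the converse. A burst whose Dex and Aex rates keep a constant
#' ratio scores near 0; acceptor bleaching or blinking inflates the score.
#'
#' @param t_dex,t_aex photon arrival times (s) of the donor-excitation and
#'   acceptor-excitation streams of one burst.
#' @param tau_kernel_s kernel time constant (s); 100 us is the conventional
#'   choice.
#' @return the score; bursts with fewer than 2 photons in either stream get
#'   the maximal-score convention 100 (flagged via attribute `degenerate`).
#' @export
alex_2cde <- function(t_dex, t_aex, tau_kernel_s = 100e-6) {
  nD <- length(t_dex); nA <- length(t_aex)
  if (nD < 2 || nA < 2)
    return(structure(100, degenerate = TRUE))
  kde_A_at_D <- kde_cross(t_dex, t_aex, tau_kernel_s)
  kde_D_at_D <- kde_cross(t_dex, t_dex, tau_kernel_s) - 1    # exclude self
  kde_D_at_A <- kde_cross(t_aex, t_dex, tau_kernel_s)
  kde_A_at_A <- kde_cross(t_aex, t_aex, tau_kernel_s) - 1
  nb_D <- (1 + 2 / nD) * kde_D_at_D
  nb_A <- (1 + 2 / nA) * kde_A_at_A
  ok_D <- nb_D > 0
  ok_A <- nb_A > 0
  br_aex <- sum(kde_A_at_D[ok_D] / nb_D[ok_D]) / nA
  br_dex <- sum(kde_D_at_A[ok_A] / nb_A[ok_A]) / nD
  100 - 50 * (br_aex + br_dex)
}

#' FRET-2CDE score of one burst
#'
#' Kernel-density estimator of FRET fluctuations within a burst, computed on
#' the donor-excitation photons only (donor = BB gates, acceptor = BR gates).
#' For donor photon i, `E_D(i) = KDE_i^A / (KDE_i^A + nbKDE_i^D)`; for
#' acceptor photon i, `(1-E)_A(i) = KDE_i^D / (KDE_i^D + nbKDE_i^A)`, with
#' the neighbour-excluded `nbKDE_i^X = (1 + 2/N_X) sum_{j != i} exp(...)`.
#' The score is `110 - 100 * (<E_D> + <(1-E)_A>)`; a static molecule scores
#' close to 10 independent of its FRET efficiency, dynamics push the score
#' up.
#'
#' @param t_dex donor-excitation photon times (s) of one burst.
#' @param acc logical, TRUE where the photon is an acceptor (BR-gate) photon.
#' @param tau_kernel_s kernel time constant (s).
#' @return the score, or `NA` when either dye has no photon.
#' @export
fret_2cde <- function(t_dex, acc, tau_kernel_s = 100e-6) {
  stopifnot(length(t_dex) == length(acc))
  nA <- sum(acc); nD <- sum(!acc)
  if (nA == 0 || nD == 0) return(NA_real_)
  tD <- t_dex[!acc]; tA <- t_dex[acc]
  kde_A_at_D <- kde_cross(tD, tA, tau_kernel_s)
  kde_D_at_D <- kde_cross(tD, tD, tau_kernel_s) - 1
  kde_D_at_A <- kde_cross(tA, tD, tau_kernel_s)
  kde_A_at_A <- kde_cross(tA, tA, tau_kernel_s) - 1
  E_D <- kde_A_at_D / (kde_A_at_D + (1 + 2 / nD) * kde_D_at_D)
  mE_A <- kde_D_at_A / (kde_D_at_A + (1 + 2 / nA) * kde_A_at_A)
  110 - 100 * (mean(E_D) + mean(mE_A))
}

# kernel matrix over all Dex photons of a burst (includes unit diagonal)
cde_kernel_matrix <- function(t_dex, tau) {
  exp(-abs(outer(t_dex, t_dex, "-")) / tau)
}

# per-burst <E_D>, <(1-E)_A> and photon numbers for R colorings at once.
# K: kernel matrix; C: n x R logical/0-1 matrix, TRUE = acceptor photon.
cde_components <- function(K, C) {
  C <- matrix(as.numeric(C), nrow(K))
  R <- ncol(C)
  rs <- rowSums(K)
  KA <- K %*% C                      # n x R: KDE^A at every photon
  KD <- rs - KA                      # KDE^D at every photon
  nA <- colSums(C)
  nD <- nrow(K) - nA
  ok <- nA > 0 & nD > 0
  fD <- rep(1, nrow(K)) %o% (1 + 2 / pmax(nD, 1))
  fA <- rep(1, nrow(K)) %o% (1 + 2 / pmax(nA, 1))
  ## donor rows: subtract self (diag 1) from own-stream KDE
  E_D <- KA / (KA + fD * (KD - 1))
  mE_A <- (KD) / (KD + fA * (KA - 1))
  Dmask <- 1 - C
  mean_E_D <- colSums(ifelse(is.finite(E_D), E_D, 0) * Dmask) / pmax(nD, 1)
  mean_mE_A <- colSums(ifelse(is.finite(mE_A), mE_A, 0) * C) / pmax(nA, 1)
  list(mean_E_D = ifelse(ok, mean_E_D, NA_real_),
       mean_mE_A = ifelse(ok, mean_mE_A, NA_real_),
       n_D = nD, n_A = nA)
}

#' Group-weighted FRET-2CDE score
#'
#' Combines per-burst kernel components over a group of bursts with photon-
#' number weights:
#' `110 - 100 * (sum N_D <E_D> / sum N_D + sum N_A <(1-E)_A> / sum N_A)`.
#'
#' @param mean_E_D,mean_mE_A,n_D,n_A per-burst components as returned by the
#'   per-burst kernel machinery.
#' @return the weighted score for the group.
#' @export
weighted_fret_2cde <- function(mean_E_D, mean_mE_A, n_D, n_A) {
  ok <- is.finite(mean_E_D) & is.finite(mean_mE_A)
  110 - 100 * (sum(n_D[ok] * mean_E_D[ok]) / sum(n_D[ok]) +
                 sum(n_A[ok] * mean_mE_A[ok]) / sum(n_A[ok]))
}

#' Re-coloring null test for FRET-2CDE
#'
#' Tests whether group-wise FRET-2CDE scores exceed what photon shot noise
#' alone produces. Bursts are grouped into `n_groups` equal FRET-efficiency
#' intervals; groups below `min_bursts` are excluded. Within each group the
#' photons of every burst are randomly re-colored (donor/acceptor) with the
#' burst's own acceptor-photon probability, destroying any within-burst FRET
#' fluctuation while preserving arrival times and mean color; the weighted
#' score of each replicate builds the null distribution. The experimental
#' weighted score is flagged when it exceeds the Bonferroni-corrected upper
#' confidence bound.
#'
#' @param photon_data per-burst photon data from [burst_photon_data()].
#' @param E per-burst corrected FRET efficiencies (grouping variable).
#' @param tau_kernel_s kernel time constant (s).
#' @param n_groups number of E intervals on `[0, 1]`.
#' @param min_bursts minimum bursts per analysed group.
#' @param repetitions number of re-coloring replicates.
#' @param alpha significance level (Bonferroni-corrected over groups).
#' @param seed integer seed for the re-coloring draws.
#' @return data.frame with one row per analysed group: `E_lo`, `E_hi`,
#'   `n_bursts`, `observed`, `null_mean`, `null_sd`, `ci_hi`, `flagged`.
#' @export
fret_2cde_null_test <- function(photon_data, E, tau_kernel_s = 100e-6,
                                n_groups = 50, min_bursts = 200,
                                repetitions = 1000, alpha = 0.001,
                                seed = NULL) {
  stopifnot(length(photon_data) == length(E))
  if (!is.null(seed)) set.seed(seed)
  brk <- seq(0, 1, length.out = n_groups + 1)
  grp <- findInterval(E, brk, rightmost.closed = TRUE)
  grp[E < 0 | E > 1] <- NA
  keep_groups <- which(tabulate(grp, n_groups) >= min_bursts)
  out <- list()
  for (g in keep_groups) {
    sel <- which(!is.na(grp) & grp == g)
    nb <- length(sel)
    comp_obs <- matrix(NA_real_, nb, 4)
    mED <- mEA <- mnD <- mnA <- matrix(NA_real_, nb, repetitions)
    for (k in seq_len(nb)) {
      p <- photon_data[[sel[k]]]
      K <- cde_kernel_matrix(p$t_dex, tau_kernel_s)
      oc <- cde_components(K, matrix(p$acc, ncol = 1))
      comp_obs[k, ] <- c(oc$mean_E_D, oc$mean_mE_A, oc$n_D, oc$n_A)
      pacc <- mean(p$acc)
      C <- matrix(stats::runif(length(p$acc) * repetitions) < pacc,
                  length(p$acc), repetitions)
      rc <- cde_components(K, C)
      mED[k, ] <- rc$mean_E_D
      mEA[k, ] <- rc$mean_mE_A
      mnD[k, ] <- rc$n_D
      mnA[k, ] <- rc$n_A
    }
    obs_score <- weighted_fret_2cde(comp_obs[, 1], comp_obs[, 2],
                                    comp_obs[, 3], comp_obs[, 4])
    ok <- is.finite(mED) & is.finite(mEA)
    mED[!ok] <- 0; mEA[!ok] <- 0
    wD <- mnD * ok; wA <- mnA * ok
    reps <- 110 - 100 * (colSums(mED * wD) / colSums(wD) +
                           colSums(mEA * wA) / colSums(wA))
    z <- stats::qnorm(1 - alpha / (2 * length(keep_groups)))
    out[[length(out) + 1L]] <- data.frame(
      E_lo = brk[g], E_hi = brk[g + 1], n_bursts = length(sel),
      observed = obs_score, null_mean = mean(reps), null_sd = stats::sd(reps),
      ci_hi = mean(reps) + z * stats::sd(reps),
      flagged = obs_score > mean(reps) + z * stats::sd(reps))
  }
  if (!length(out)) return(data.frame())
  do.call(rbind, out)
}
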